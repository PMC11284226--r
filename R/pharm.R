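# Multiparametric pharmacological fingerprint: percent-change features from
# the serial stimulation protocol, mean-padding imputation, standardization
# to mean 0 / SD 1, PCA, and a convex-hull overlap percentage between two
# groups in a 2D component projection.

feature_defs <- list(
  f1 = c("NMDA_gly", "baseline1"),
  f2 = c("D_AP5", "NMDA_gly"),
  f3 = c("AMPA", "baseline2"),
  f4 = c("CNQX", "AMPA")
)

#' Build serial-stimulation feature vectors
#'
#' Per network and compartment: f1 = percent change of NMDA + glycine vs
#' baseline 1, f2 = D-AP5 vs NMDA + glycine, f3 = AMPA vs baseline 2,
#' f4 = CNQX vs AMPA. Conventional layouts give 4 features; tripartite
#' layouts give 12 in the fixed order proximal f1-f4, distal1 f1-f4,
#' distal2 f1-f4. A feature with a missing (or zero-denominator) operand
#' is `NA`.
#'
#' @param rates Long tibble with `network_id`, `group`, `compartment`,
#'   `condition`, `rate_hz` (e.g. from [simulate_pharm_experiment()] or
#'   [read_table()] with the rates schema).
#' @return Wide tibble: `network_id`, `group`, then the feature columns
#'   (percent units).
#' @export
build_features <- function(rates) {
  need <- c("network_id", "group", "compartment", "condition", "rate_hz")
  missing_cols <- setdiff(need, names(rates))
  if (length(missing_cols) > 0) {
    if (identical(missing_cols, "compartment")) {
      rates$compartment <- "single"
    } else {
      abort(paste0("rates table missing: ", paste(missing_cols, collapse = ", ")))
    }
  }
  wide <- tidyr::pivot_wider(
    dplyr::select(rates, dplyr::all_of(need)),
    names_from = "condition", values_from = "rate_hz")
  for (cond in pharm_conditions) {
    if (!cond %in% names(wide)) wide[[cond]] <- NA_real_
  }
  feats <- wide[, c("network_id", "group", "compartment")]
  for (f in names(feature_defs)) {
    op <- feature_defs[[f]]
    feats[[f]] <- percent_change(wide[[op[1]]], wide[[op[2]]])
  }
  comps <- unique(feats$compartment)
  if (length(comps) == 1) {
    out <- dplyr::select(feats, -"compartment")
  } else {
    order_comps <- intersect(c("proximal", "distal1", "distal2"), comps)
    order_comps <- c(order_comps, setdiff(comps, order_comps))
    long <- tidyr::pivot_longer(feats, dplyr::all_of(names(feature_defs)),
                                names_to = "feature", values_to = "value")
    long$col <- paste(long$compartment, long$feature, sep = "_")
    col_order <- as.vector(t(outer(order_comps, names(feature_defs), paste, sep = "_")))
    out <- tidyr::pivot_wider(dplyr::select(long, "network_id", "group", "col", "value"),
                              names_from = "col", values_from = "value")
    out <- out[, c("network_id", "group", col_order)]
  }
  out
}

#' Mean-padding imputation and standardization
#'
#' Each missing cell is replaced by its column mean over the observed values
#' (both groups pooled), then every column is centered and scaled by its
#' population (divide-by-n) standard deviation, so standardized columns have
#' mean 0 and SD 1 exactly. Constant columns are flagged and left centered.
#'
#' @param features Wide feature tibble from [build_features()] (id columns
#'   `network_id`, `group` are carried through untouched).
#' @return List: `standardized` (tibble), `imputation` (tibble of filled
#'   cells: row, column, fill value), `center`, `scale`,
#'   `constant_columns`.
#' @export
impute_standardize <- function(features) {
  id_cols <- intersect(c("network_id", "group"), names(features))
  num_cols <- setdiff(names(features), id_cols)
  x <- as.matrix(features[, num_cols])
  if (nrow(x) < 2) abort("need at least 2 rows to standardize")
  if (any(colSums(!is.na(x)) == 0)) {
    abort("column(s) with no observed values cannot be mean-padded")
  }
  fills <- which(is.na(x), arr.ind = TRUE)
  col_means <- colMeans(x, na.rm = TRUE)
  imput <- tibble(row = integer(0), column = character(0), value = numeric(0))
  if (nrow(fills) > 0) {
    x[fills] <- col_means[fills[, 2]]
    imput <- tibble(row = as.integer(fills[, 1]),
                    column = num_cols[fills[, 2]],
                    value = unname(col_means[fills[, 2]]))
  }
  ctr <- colMeans(x)
  scl <- sqrt(colMeans(sweep(x, 2, ctr)^2)) # population SD
  const <- num_cols[scl == 0]
  scl_use <- ifelse(scl == 0, 1, scl)
  z <- sweep(sweep(x, 2, ctr), 2, scl_use, "/")
  out <- dplyr::bind_cols(features[, id_cols],
                          as_tibble(as.data.frame(z, optional = TRUE)))
  list(standardized = out, imputation = imput, center = ctr, scale = scl,
       constant_columns = const)
}

#' PCA embedding of the standardized feature matrix
#'
#' Singular-value decomposition of the standardized matrix; scores on the
#' first `n_components` directions of maximal variance with a deterministic
#' sign convention (the largest-magnitude loading of each component is made
#' positive). Explained-variance fractions are eigenvalue shares.
#'
#' @param standardized Tibble from [impute_standardize()]'s `standardized`
#'   element (or any tibble whose non-id columns are the matrix).
#' @param n_components Number of components to keep.
#' @return An `embedding_result`: `scores` tibble (ids + `PC1`, `PC2`, ...),
#'   `loadings` matrix, `explained_variance` fractions (all components),
#'   `n_components`.
#' @export
pca_embed <- function(standardized, n_components = 3) {
  id_cols <- intersect(c("network_id", "group"), names(standardized))
  num_cols <- setdiff(names(standardized), id_cols)
  x <- as.matrix(standardized[, num_cols])
  if (nrow(x) < n_components) {
    abort("fewer rows than requested components")
  }
  pc <- prcomp(x, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pc$rotation))
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    l <- pc$rotation[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  out <- dplyr::bind_cols(
    standardized[, id_cols],
    as_tibble(as.data.frame(scores[, seq_len(k), drop = FALSE])))
  structure(list(scores = out, loadings = rot[, seq_len(k), drop = FALSE],
                 explained_variance = ev, n_components = k),
            class = "embedding_result")
}

#' @export
print.embedding_result <- function(x, ...) {
  cat(sprintf("<embedding_result> %d rows, %d components (%.1f%%, %s)\n",
              nrow(x$scores), x$n_components,
              100 * sum(x$explained_variance[seq_len(x$n_components)]),
              paste(sprintf("%.1f%%", 100 * x$explained_variance[seq_len(x$n_components)]),
                    collapse = " + ")))
  invisible(x)
}

# signed area (shoelace); positive for counter-clockwise vertex order
polygon_signed_area <- function(p) {
  n <- nrow(p)
  if (n < 3) return(0)
  i2 <- c(2:n, 1)
  sum(p[, 1] * p[i2, 2] - p[i2, 1] * p[, 2]) / 2
}

# convex hull of 2D points as a counter-clockwise vertex matrix
convex_hull_ccw <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) < 3) return(pts)
  h <- pts[chull(pts), , drop = FALSE]
  if (polygon_signed_area(h) < 0) h <- h[rev(seq_len(nrow(h))), , drop = FALSE]
  h
}

# Sutherland-Hodgman: clip convex polygon `subject` by convex CCW `clip`
clip_convex <- function(subject, clip) {
  out <- subject
  nc <- nrow(clip)
  for (e in seq_len(nc)) {
    if (nrow(out) == 0) return(out)
    a <- clip[e, ]; b <- clip[e %% nc + 1, ]
    inside <- function(p) (b[1] - a[1]) * (p[2] - a[2]) -
      (b[2] - a[2]) * (p[1] - a[1]) >= 0
    inp <- out
    out <- matrix(numeric(0), ncol = 2)
    n <- nrow(inp)
    for (i in seq_len(n)) {
      cur <- inp[i, ]; prev <- inp[(i - 2) %% n + 1, ]
      cur_in <- inside(cur); prev_in <- inside(prev)
      if (cur_in) {
        if (!prev_in) out <- rbind(out, segment_intersect(prev, cur, a, b))
        out <- rbind(out, cur)
      } else if (prev_in) {
        out <- rbind(out, segment_intersect(prev, cur, a, b))
      }
    }
  }
  out
}

segment_intersect <- function(p1, p2, a, b) {
  d1 <- p2 - p1; d2 <- b - a
  denom <- d1[1] * d2[2] - d1[2] * d2[1]
  t <- ((a[1] - p1[1]) * d2[2] - (a[2] - p1[2]) * d2[1]) / denom
  p1 + t * d1
}

#' Overlap percentage of two point clouds in a 2D projection
#'
#' Convex hulls of each group's projected points; their intersection by
#' convex clipping; overlap = 100 * intersection area / smaller hull area.
#' Groups with fewer than 3 distinct non-collinear projected points give a
#' degenerate (flagged) result instead of a number.
#'
#' @param scores_a,scores_b Numeric matrices (or score tibbles from
#'   [pca_embed()]) for the two groups.
#' @param plane Length-2 integer vector or column names selecting the
#'   projection plane (default the first two components).
#' @return An `overlap_result`: hull vertex matrices, hull areas,
#'   intersection area and polygon, `overlap_percent`, `degenerate`.
#' @export
overlap_percentage <- function(scores_a, scores_b, plane = c(1, 2)) {
  proj <- function(s) {
    if (is.data.frame(s)) s <- as.matrix(s[, grep("^PC", names(s)), drop = FALSE])
    unname(as.matrix(s[, plane, drop = FALSE]))
  }
  pa <- proj(scores_a); pb <- proj(scores_b)
  ha <- convex_hull_ccw(pa); hb <- convex_hull_ccw(pb)
  area_a <- polygon_signed_area(ha); area_b <- polygon_signed_area(hb)
  if (nrow(ha) < 3 || nrow(hb) < 3 || area_a <= 0 || area_b <= 0) {
    return(structure(list(hull_a = ha, hull_b = hb, area_a = area_a,
                          area_b = area_b, intersection = NULL,
                          intersection_area = NA_real_,
                          overlap_percent = NA_real_, degenerate = TRUE),
                     class = "overlap_result"))
  }
  # canonical clip order makes the result exactly symmetric in group order
  key <- function(h) paste(apply(h[order(h[, 1], h[, 2]), , drop = FALSE], 1,
                                 paste, collapse = ","), collapse = ";")
  if (key(ha) <= key(hb)) {
    inter <- clip_convex(ha, hb)
  } else {
    inter <- clip_convex(hb, ha)
  }
  ia <- if (nrow(inter) >= 3) abs(polygon_signed_area(inter)) else 0
  structure(list(hull_a = ha, hull_b = hb, area_a = area_a, area_b = area_b,
                 intersection = inter, intersection_area = ia,
                 overlap_percent = 100 * ia / min(area_a, area_b),
                 degenerate = FALSE),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  if (x$degenerate) {
    cat("<overlap_result> degenerate geometry (overlap undefined)\n")
  } else {
    cat(sprintf("<overlap_result> %.1f%% (areas %.3g / %.3g, intersection %.3g)\n",
                x$overlap_percent, x$area_a, x$area_b, x$intersection_area))
  }
  invisible(x)
}

#' Full fingerprint pipeline: features to group overlap
#'
#' Runs [build_features()], [impute_standardize()] and [pca_embed()] on the
#' pooled rows, then computes the control-vs-treated overlap percentage in
#' the configured projection plane.
#'
#' @param rates Long rates tibble (both groups).
#' @param config A [neuract_config()].
#' @return A `fingerprint_result`: `features`, `embedding`
#'   (an `embedding_result` with the imputation report attached), `overlap`
#'   (an `overlap_result`), and per-group sample sizes.
#' @export
run_fingerprint <- function(rates, config = neuract_config()) {
  feats <- build_features(rates)
  groups <- unique(feats$group)
  if (length(groups) < 2) {
    abort(paste0("both groups must be present; found: ",
                 paste(groups, collapse = ", ")))
  }
  std <- impute_standardize(feats)
  emb <- pca_embed(std$standardized, config$pharm$n_components)
  emb$imputation <- std$imputation
  plane <- config$pharm$overlap_projection_axes
  ov <- overlap_percentage(dplyr::filter(emb$scores, .data$group == groups[1]),
                           dplyr::filter(emb$scores, .data$group == groups[2]),
                           plane = plane)
  structure(list(features = feats, embedding = emb, overlap = ov,
                 n_per_group = table(feats$group), plane = plane),
            class = "fingerprint_result")
}

#' @export
print.fingerprint_result <- function(x, ...) {
  cat("<fingerprint_result>\n  groups:",
      paste(names(x$n_per_group), x$n_per_group, sep = "=", collapse = ", "),
      "\n")
  print(x$embedding)
  print(x$overlap)
  invisible(x)
}
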