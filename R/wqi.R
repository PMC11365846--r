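# Integrated-weight drinking water quality index.
#
# Two objective weighting schemes are combined: Shannon-entropy weights
# (parameters whose normalized column carries more information weigh more)
# and CRITIC weights (standard deviation times non-redundancy, i.e. the sum
# of 1 - Pearson correlation with the other parameters). The index itself
# is the weighted sum of per-parameter quality ratings
# Qj = 100 (Cj - Cjp)/(Sj - Cjp) evaluated against WHO standards.

#' Min-max normalize the parameter matrix
#'
#' `Yij = (Xij - min_j) / (max_j - min_j)` columnwise. A zero-range
#' (constant) column carries no information: it is set to all zeros with a
#' warning, and downstream weighting assigns it weight 0.
#'
#' @param x numeric matrix or data.frame (m samples x n parameters), m >= 2.
#' @return numeric matrix in `[0, 1]` with attributes `column_min`,
#'   `column_max`, `degenerate` (logical per column).
#' @export
normalize_matrix <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 samples to normalize", call. = FALSE)
  cmin <- apply(x, 2, min)
  cmax <- apply(x, 2, max)
  rng <- cmax - cmin
  degen <- rng == 0
  if (any(degen)) {
    warning("degenerate (constant) column(s): ",
            paste(colnames(x)[degen], collapse = ", "), call. = FALSE)
    rng[degen] <- 1 # avoid 0/0; numerator is 0 anyway
  }
  y <- sweep(sweep(x, 2, cmin, "-"), 2, rng, "/")
  structure(y, column_min = cmin, column_max = cmax, degenerate = degen)
}

#' Shannon entropy weights
#'
#' For each column: `Pij = Yij / sum_i(Yij)`,
#' `ej = -(1/ln m) sum_i(Pij ln Pij)` (with `0 ln 0 := 0`), and
#' `wj1 = (1 - ej) / sum_j(1 - ej)`. Degenerate columns get `ej = 1`
#' (zero information) and hence weight 0.
#'
#' @param y normalized matrix from [normalize_matrix()].
#' @param detail if `TRUE`, return a list with the entropies `ej` as well.
#' @return weight vector summing to 1 (or a list when `detail = TRUE`).
#' @export
entropy_weights <- function(y, detail = FALSE) {
  y <- as.matrix(y)
  m <- nrow(y)
  degen <- attr(y, "degenerate")
  if (is.null(degen)) degen <- apply(y, 2, function(col) max(col) == min(col))
  ej <- vapply(seq_len(ncol(y)), function(j) {
    if (degen[j]) return(1)
    s <- sum(y[, j])
    if (s == 0) return(1)
    p <- y[, j] / s
    terms <- ifelse(p > 0, p * log(p), 0)
    -sum(terms) / log(m)
  }, numeric(1))
  d <- 1 - ej
  if (sum(d) <= 0) stop("all columns degenerate: entropy weights undefined",
                        call. = FALSE)
  w <- d / sum(d)
  names(w) <- colnames(y)
  if (detail) list(wj1 = w, ej = stats::setNames(ej, colnames(y))) else w
}

#' CRITIC weights (criteria importance through inter-criteria correlation)
#'
#' `Sj = delta_j * sum_k (1 - r_jk)` where `delta_j` is the column standard
#' deviation of the normalized matrix and `r` its Pearson correlation
#' matrix; `wj2 = Sj / sum(Sj)`. Zero-variance columns have undefined
#' correlations; their correlations are set to 0 (with `delta_j = 0` the
#' column still gets weight 0) and a warning is raised.
#'
#' @param y normalized matrix (m >= 3 for meaningful correlations).
#' @param detail if `TRUE`, also return `sj_info`, `delta`, `r`.
#' @return weight vector summing to 1 (or a list when `detail = TRUE`).
#' @export
critic_weights <- function(y, detail = FALSE) {
  y <- as.matrix(y)
  delta <- apply(y, 2, stats::sd)
  r <- suppressWarnings(stats::cor(y, use = "pairwise.complete.obs"))
  if (any(delta == 0)) {
    warning("zero-variance column(s): correlations set to 0 for ",
            paste(colnames(y)[delta == 0], collapse = ", "), call. = FALSE)
  }
  r[!is.finite(r)] <- 0
  sj <- delta * rowSums(1 - r)
  if (sum(sj) <= 0) {
    # fully redundant criteria (all pairwise r = 1): no column carries
    # unique information, split the weight evenly over the varying columns
    if (all(delta == 0)) {
      stop("CRITIC weights undefined: no information in matrix",
           call. = FALSE)
    }
    w <- as.numeric(delta > 0) / sum(delta > 0)
    names(w) <- colnames(y)
    if (detail) return(list(wj2 = w, sj_info = sj, delta = delta, r = r))
    return(w)
  }
  w <- sj / sum(sj)
  names(w) <- colnames(y)
  if (detail) list(wj2 = w, sj_info = sj, delta = delta, r = r) else w
}

#' Combine entropy and CRITIC weights
#'
#' `method = "product"` (default): `Wj = wj1 wj2 / sum(wj1 wj2)`, which is
#' self-normalizing. `method = "convex"`: `Wj = p wj1 + (1 - p) wj2` for a
#' preference coefficient `p` in `[0, 1]`.
#'
#' @param wj1,wj2 weight vectors of equal length, each summing to 1.
#' @param method `"product"` or `"convex"`.
#' @param p preference coefficient for the convex rule.
#' @return integrated weight vector summing to 1.
#' @export
integrate_weights <- function(wj1, wj2, method = c("product", "convex"),
                              p = 0.5) {
  method <- match.arg(method)
  stopifnot(length(wj1) == length(wj2))
  if (method == "convex") {
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("p must be in [0, 1]", call. = FALSE)
    }
    w <- p * wj1 + (1 - p) * wj2
  } else {
    prod <- wj1 * wj2
    if (sum(prod) <= 0) stop("degenerate product weights", call. = FALSE)
    w <- prod / sum(prod)
  }
  w
}

#' Per-parameter quality ratings
#'
#' `Qj = 100 (Cj - Cjp)/(Sj - Cjp)`: 0 at the pure-water ideal, 100 at the
#' WHO standard. For pH the ideal is 7 and the standard 7.5, so acidic
#' samples get a signed negative rating (the formula is applied as stated,
#' without taking absolute values).
#'
#' @param tbl sample table (or data.frame carrying the evaluated columns).
#' @param standards standards table, see [default_standards()].
#' @param parameters evaluated parameters (default: those in `standards`).
#' @return matrix m x n of ratings (%).
#' @export
quality_rating <- function(tbl, standards = default_standards(),
                           parameters = standards$parameter) {
  miss <- setdiff(parameters, standards$parameter)
  if (length(miss)) stop("no standard for: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  miss <- setdiff(parameters, names(tbl))
  if (length(miss)) stop("sample table lacks column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  idx <- match(parameters, standards$parameter)
  sj <- standards$sj[idx]; cjp <- standards$cjp[idx]
  if (any(sj == cjp)) stop("Sj equals Cjp for ",
                           paste(parameters[sj == cjp], collapse = ", "),
                           call. = FALSE)
  q <- vapply(seq_along(parameters), function(j) {
    100 * (tbl[[parameters[j]]] - cjp[j]) / (sj[j] - cjp[j])
  }, numeric(nrow(tbl)))
  q <- matrix(q, nrow = nrow(tbl),
              dimnames = list(tbl$sample_id, parameters))
  q
}

#' Compute the integrated-weight water quality index
#'
#' `WQI = sum_j Wj Qj` per sample, classified with [wqi_scheme()].
#'
#' @param tbl sample table.
#' @param weights named weight vector over the evaluated parameters
#'   (must sum to 1); default: the published integrated weights.
#' @param standards standards table.
#' @param scheme classification scheme for the labels.
#' @return data.frame `sample_id`, `wqi`, `label`, with the rating matrix
#'   attached as attribute `qj`.
#' @export
compute_wqi <- function(tbl, weights = NULL,
                        standards = default_standards(),
                        scheme = wqi_scheme()) {
  if (is.null(weights)) {
    weights <- stats::setNames(standards$wj, standards$parameter)
  }
  if (is.null(names(weights))) stop("weights must be named", call. = FALSE)
  if (abs(sum(weights) - 1) > 1e-6) {
    stop("weights must sum to 1 (got ", format(sum(weights)), ")",
         call. = FALSE)
  }
  q <- quality_rating(tbl, standards, parameters = names(weights))
  wqi <- as.numeric(q %*% weights)
  out <- data.frame(sample_id = tbl$sample_id, wqi = wqi,
                    label = classify_value(wqi, scheme),
                    stringsAsFactors = FALSE)
  attr(out, "qj") <- q
  out
}

#' Entropy + CRITIC weighting of a cohort
#'
#' Runs the full objective-weighting chain on the cohort's measured matrix:
#' normalization, entropy weights, CRITIC weights and their integration.
#'
#' @param tbl sample table.
#' @param parameters evaluated parameters (default: the 14-parameter set).
#' @param integration `"product"` or `"convex"`.
#' @param p preference coefficient for `"convex"`.
#' @return list with `wj1`, `wj2`, `wj`, `ej`, `sj_info`, `delta`, `r`,
#'   `method`, `p`.
#' @export
cohort_weights <- function(tbl, parameters = WQI_PARAMETERS,
                           integration = c("product", "convex"), p = 0.5) {
  integration <- match.arg(integration)
  x <- as.matrix(as.data.frame(tbl)[, parameters, drop = FALSE])
  y <- normalize_matrix(x)
  ent <- entropy_weights(y, detail = TRUE)
  cri <- critic_weights(y, detail = TRUE)
  wj <- integrate_weights(ent$wj1, cri$wj2, method = integration, p = p)
  list(wj1 = ent$wj1, wj2 = cri$wj2, wj = wj, ej = ent$ej,
       sj_info = cri$sj_info, delta = cri$delta, r = cri$r,
       method = integration, p = if (integration == "convex") p else NA_real_)
}
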