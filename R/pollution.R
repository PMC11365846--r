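# Heavy-metal pollution index (HPI) and Hakanson ecological risk index (RI).

#' Heavy-metal pollution index
#'
#' `HPI = sum(Wi Qi) / sum(Wi)` with rating weight `Wi = 1/Si` and
#' sub-index `Qi = 100 Ci / Si`, where `Si` is the drinking standard for
#' metal i. With every metal exactly at its standard the index is 100
#' regardless of the metal set. The default metal set is Fe and Mn, the
#' two elements the source screening targets.
#'
#' @param tbl sample table.
#' @param metals metals to include (subset of the toxicity table).
#' @param toxicity toxicity table, see [default_toxicity()].
#' @return data.frame `sample_id`, `hpi`, `label` (via [hpi_scheme()]).
#' @export
#' @examples
#' # at-standard water scores exactly 100
#' tbl <- generate_cohort(n = 3, seed = 1)
#' tbl$Fe <- 0.3; tbl$Mn <- 0.1
#' hpi(tbl)$hpi
hpi <- function(tbl, metals = c("Fe", "Mn"), toxicity = default_toxicity()) {
  miss <- setdiff(metals, toxicity$metal)
  if (length(miss)) stop("no toxicity entry for metal(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  miss <- setdiff(metals, names(tbl))
  if (length(miss)) stop("missing metal concentration column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  si <- toxicity$si[match(metals, toxicity$metal)]
  if (any(!is.finite(si) | si <= 0)) {
    stop("Si must be positive for all metals", call. = FALSE)
  }
  wi <- 1 / si
  ci <- as.matrix(as.data.frame(tbl)[, metals, drop = FALSE])
  qi <- sweep(ci, 2, si, "/") * 100
  h <- as.numeric(qi %*% wi) / sum(wi)
  data.frame(sample_id = tbl$sample_id, hpi = h,
             label = classify_hpi(h), stringsAsFactors = FALSE)
}

#' Classify an HPI value
#' @param x numeric HPI values (>= 0).
#' @return character labels, see [hpi_scheme()].
#' @export
classify_hpi <- function(x) classify_value(x, hpi_scheme())

#' Hakanson ecological risk index
#'
#' Per-metal risk `Er_i = Tr_i * Ci / Cbg_i` (toxic-response factor times
#' enrichment over the site background) and total `RI = sum_i Er_i`.
#' Backgrounds are site-specific and must be present in the toxicity table
#' (`c_bg`); there is deliberately no silent default.
#'
#' @param tbl sample table.
#' @param toxicity toxicity table with `tr` and `c_bg` populated.
#' @param metals metals to include.
#' @return data.frame with `sample_id`, one `er_<metal>` column per metal,
#'   `ri` and `label` (via [ri_scheme()]).
#' @export
ecological_risk <- function(tbl, toxicity, metals = toxicity$metal) {
  idx <- match(metals, toxicity$metal)
  if (any(is.na(idx))) stop("no toxicity entry for metal(s): ",
                            paste(metals[is.na(idx)], collapse = ", "),
                            call. = FALSE)
  tr <- toxicity$tr[idx]; cbg <- toxicity$c_bg[idx]
  if (any(is.na(tr))) stop("missing toxic-response factor Tr", call. = FALSE)
  if (any(is.na(cbg) | cbg <= 0)) {
    stop("background concentration c_bg missing or non-positive for: ",
         paste(metals[is.na(cbg) | cbg <= 0], collapse = ", "),
         "; supply site backgrounds in the toxicity table", call. = FALSE)
  }
  ci <- as.matrix(as.data.frame(tbl)[, metals, drop = FALSE])
  er <- sweep(sweep(ci, 2, cbg, "/"), 2, tr, "*")
  colnames(er) <- paste0("er_", metals)
  ri <- rowSums(er)
  out <- data.frame(sample_id = tbl$sample_id, er,
                    ri = ri, label = classify_ri(ri),
                    stringsAsFactors = FALSE)
  out
}

#' Classify an ecological risk index value
#' @param x numeric RI values (>= 0).
#' @return character labels, see [ri_scheme()].
#' @export
classify_ri <- function(x) classify_value(x, ri_scheme())
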