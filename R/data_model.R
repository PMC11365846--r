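# Sample-table container, CSV I/O, interval classification and config
# loading. A sample table is a plain data.frame (one row per well) with a
# "sample_table" class tag; columns: sample_id, optional easting/northing,
# pH, EC, TDS, TH, the major ions and the trace metals, all in mg/L except
# EC (uS/cm) and pH.

SAMPLE_COLUMNS <- c("pH", "EC", "TDS", "TH", ION_NAMES, PTE_NAMES)

#' Assemble and validate a sample table
#'
#' @param df data.frame with a `sample_id` column plus the measured columns
#'   (`pH`, `EC`, `TDS`, `TH`, ions `Ca`...`NO3`, metals `Fe`...`Zn`).
#'   A missing `CO3` column is treated as 0 (routinely below detection).
#' @return the validated data.frame, classed `"sample_table"`.
#' @export
sample_table <- function(df) {
  stopifnot(is.data.frame(df))
  if (!"sample_id" %in% names(df)) {
    df$sample_id <- paste0("S", seq_len(nrow(df)))
  }
  if (!"CO3" %in% names(df)) df$CO3 <- 0
  missing_cols <- setdiff(SAMPLE_COLUMNS, names(df))
  if (length(missing_cols)) {
    stop("sample table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (col in SAMPLE_COLUMNS) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      stop("column '", col, "' is not numeric", call. = FALSE)
    }
    bad <- which(!is.na(v) & v < 0)
    if (col != "pH" && length(bad)) {
      stop("negative concentration in column '", col, "' for sample ",
           df$sample_id[bad[1]], call. = FALSE)
    }
  }
  out_ph <- which(!is.na(df$pH) & (df$pH <= 0 | df$pH >= 14))
  if (length(out_ph)) {
    stop("pH out of (0, 14) for sample ", df$sample_id[out_ph[1]],
         call. = FALSE)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Read a sample table from CSV
#'
#' Comma-separated, UTF-8, one header row. `column_map` lets arbitrary
#' headers be mapped onto the canonical names, e.g.
#' `c(Cl = "chloride_mg_l")`. Unparseable numerics are an error, never a
#' silent `NA`.
#'
#' @param path CSV file path.
#' @param column_map named character vector, canonical name -> file header.
#' @return a [sample_table()].
#' @export
read_samples <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e) stop("empty or unreadable sample file: ", path,
                             " (", conditionMessage(e), ")", call. = FALSE))
  if (!nrow(df) || !ncol(df)) stop("empty sample file: ", path, call. = FALSE)
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      hdr <- column_map[[canon]]
      if (!hdr %in% names(df)) {
        stop("column '", hdr, "' (mapped to ", canon, ") not found in ", path,
             call. = FALSE)
      }
      names(df)[names(df) == hdr] <- canon
    }
  }
  present <- intersect(SAMPLE_COLUMNS, names(df))
  for (col in present) {
    if (is.character(df[[col]])) {
      parsed <- suppressWarnings(as.numeric(df[[col]]))
      bad <- which(is.na(parsed) & !is.na(df[[col]]) & nzchar(df[[col]]))
      if (length(bad)) {
        stop("unparseable numeric '", df[[col]][bad[1]], "' in column '",
             col, "' (row ", bad[1], ")", call. = FALSE)
      }
      df[[col]] <- parsed
    }
  }
  sample_table(df)
}

#' Write a sample table to CSV
#' @param tbl a sample table.
#' @param path output path.
#' @export
write_samples <- function(tbl, path) {
  utils::write.csv(as.data.frame(tbl), path, row.names = FALSE)
  invisible(path)
}

# ---- interval classification ------------------------------------------------

#' Build an interval classification scheme
#'
#' Partitions the whole real line into `length(breakpoints) + 1` labelled
#' bins. The default edge rule is lower-inclusive (`[a, b)`), chosen because
#' published verbal bin definitions in this literature overlap or abut
#' inconsistently; one deterministic rule is applied everywhere.
#'
#' @param breakpoints strictly increasing numeric vector.
#' @param labels character vector, one longer than `breakpoints`.
#' @param right if `TRUE`, bins are `(a, b]` instead of `[a, b)`.
#' @return an object of class `"classification_scheme"`.
#' @export
classification_scheme <- function(breakpoints, labels, right = FALSE) {
  breakpoints <- as.numeric(breakpoints)
  if (any(diff(breakpoints) <= 0)) {
    stop("breakpoints must be strictly increasing", call. = FALSE)
  }
  if (length(labels) != length(breakpoints) + 1L) {
    stop("need exactly one more label than breakpoints", call. = FALSE)
  }
  structure(list(breakpoints = breakpoints, labels = as.character(labels),
                 right = isTRUE(right)),
            class = "classification_scheme")
}

#' Classify values against a scheme
#'
#' Total and deterministic over the reals: every finite value gets exactly
#' one label. `NaN`/`NA` input is an error.
#'
#' @param x numeric vector.
#' @param scheme a [classification_scheme()].
#' @return character vector of labels.
#' @export
#' @examples
#' classify_value(29.57, wqi_scheme())   # "excellent"
#' classify_value(286.3, wqi_scheme())   # "extremely poor"
classify_value <- function(x, scheme) {
  stopifnot(inherits(scheme, "classification_scheme"))
  if (any(is.na(x))) stop("cannot classify NA/NaN values", call. = FALSE)
  idx <- findInterval(x, scheme$breakpoints,
                      left.open = scheme$right,
                      rightmost.closed = FALSE) + 1L
  scheme$labels[idx]
}

#' Built-in classification schemes
#'
#' `wqi_scheme()`: 0-50 excellent, 50-100 good, 100-150 medium, 150-200
#' poor, >200 extremely poor. `hpi_scheme()`: the gap-free reconciliation
#' [0,15) excellent, [15,30) good, [30,51) intermediate, [51,76) poor,
#' [76,100) very poor, >=100 unsuitable. `ri_scheme()`: <30 low, 30-60
#' moderate, 60-120 significant, >120 very high. `hq_scheme()`: <=1 safe,
#' >1 potential risk (upper-exclusive on the threshold so exactly 1 is
#' safe, matching the strict `> 1` exceedance convention).
#'
#' @return a [classification_scheme()].
#' @export
wqi_scheme <- function() {
  classification_scheme(c(50, 100, 150, 200),
                        c("excellent", "good", "medium", "poor",
                          "extremely poor"))
}

#' @rdname wqi_scheme
#' @export
hpi_scheme <- function() {
  classification_scheme(c(15, 30, 51, 76, 100),
                        c("excellent", "good", "intermediate", "poor",
                          "very poor", "unsuitable"))
}

#' @rdname wqi_scheme
#' @export
ri_scheme <- function() {
  classification_scheme(c(30, 60, 120),
                        c("low", "moderate", "significant", "very high"))
}

#' @rdname wqi_scheme
#' @export
hq_scheme <- function() {
  classification_scheme(1, c("safe", "potential risk"), right = TRUE)
}

# ---- configuration ----------------------------------------------------------

#' Load a JSON configuration, merged over package defaults
#'
#' The config file may override any subset of: `standards` (rows keyed by
#' `parameter` with `sj`/`cjp`/`wj`), `toxicity` (rows keyed by `metal` with
#' `si`/`tr`/`rfd_oral`/`abs_gi`/`kp`/`c_bg`), `exposure` (rows keyed by
#' `cohort`), `schemes` (named lists with `breakpoints`/`labels`), and
#' scalar options (`cai_numerator`, `wqi_integration`, `wqi_p`,
#' `hpi_metals`). Unknown parameter or metal names are an error listing the
#' valid names. When `rfd_dermal` is not supplied it is derived as
#' `rfd_oral * abs_gi`.
#'
#' @param path JSON file, or `NULL` for pure defaults.
#' @return list with elements `standards`, `toxicity`, `exposure`,
#'   `schemes`, `options`.
#' @export
load_config <- function(path = NULL) {
  cfg <- list(
    standards = default_standards(),
    toxicity = default_toxicity(),
    exposure = default_exposure(),
    schemes = list(wqi = wqi_scheme(), hpi = hpi_scheme(),
                   ri = ri_scheme(), hq = hq_scheme()),
    options = list(cai_numerator = "schoeller",
                   wqi_integration = "product", wqi_p = 0.5,
                   hpi_metals = c("Fe", "Mn"))
  )
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  user <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)

  merge_keyed <- function(base, upd, key, what) {
    upd <- as.data.frame(upd, stringsAsFactors = FALSE)
    unknown <- setdiff(upd[[key]], base[[key]])
    if (length(unknown)) {
      stop("unknown ", what, ": ", paste(unknown, collapse = ", "),
           "; valid names are ", paste(base[[key]], collapse = ", "),
           call. = FALSE)
    }
    for (i in seq_len(nrow(upd))) {
      row <- match(upd[[key]][i], base[[key]])
      for (col in setdiff(names(upd), key)) {
        if (!col %in% names(base)) base[[col]] <- NA_real_
        if (!is.na(upd[[col]][i])) base[row, col] <- upd[[col]][i]
      }
    }
    base
  }

  if (!is.null(user$standards)) {
    cfg$standards <- merge_keyed(cfg$standards, user$standards,
                                 "parameter", "parameter name(s)")
  }
  if (!is.null(user$toxicity)) {
    had_dermal <- "rfd_dermal" %in% names(as.data.frame(user$toxicity))
    cfg$toxicity <- merge_keyed(cfg$toxicity, user$toxicity,
                                "metal", "metal name(s)")
    if (!had_dermal) {
      cfg$toxicity$rfd_dermal <- rfd_dermal(cfg$toxicity$rfd_oral,
                                            cfg$toxicity$abs_gi)
    }
  }
  if (!is.null(user$exposure)) {
    cfg$exposure <- merge_keyed(cfg$exposure, user$exposure,
                                "cohort", "cohort name(s)")
  }
  if (!is.null(user$schemes)) {
    for (nm in names(user$schemes)) {
      sc <- user$schemes[[nm]]
      cfg$schemes[[nm]] <- classification_scheme(sc$breakpoints, sc$labels,
                                                 right = isTRUE(sc$right))
    }
  }
  for (opt in intersect(names(user), names(cfg$options))) {
    cfg$options[[opt]] <- user[[opt]]
  }
  cfg
}
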