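#' Validate a NONMEM-style PK dataset
#'
#' A dataset is a data frame with one row per dose or observation and
#' columns:
#'
#' * `ID` — subject identifier,
#' * `TIME` — hours since the subject's first dose, non-negative and
#'   non-decreasing within subject (ties allowed: a trough sample recorded at
#'   the dose instant precedes the dose row),
#' * `EVID` — 1 for dose rows, 0 for observation rows,
#' * `AMT` — dose amount (mg) on dose rows, `NA` otherwise,
#' * `MDV` — missing-DV flag (1 on dose rows),
#' * `DV` — observed whole-blood concentration (ng/mL, observed scale),
#' * `HCT` — hematocrit (%) at the observation's occasion,
#' * `AGE`, `BW`, `CYP3A5` (1 carrier / 0 non-carrier), `DAY` (occasion).
#'
#' Concentrations are stored on the observed scale only; hematocrit-45
#' standardization is always recomputed from `HCT`, never persisted.
#'
#' @param data Data frame to validate.
#' @return The validated data (as a tibble), invisibly usable downstream.
#'   Violations raise an error naming the offending rows.
#' @export
validate_pk_dataset <- function(data) {
  req <- c("ID", "TIME", "EVID", "AMT", "MDV", "DV", "HCT", "AGE", "BW",
           "CYP3A5", "DAY")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  d <- tibble::as_tibble(data)
  problems <- character()
  bad_rows <- function(ok, msg) {
    if (any(!ok)) {
      problems <<- c(problems, paste0(
        msg, " (rows ", paste(utils::head(which(!ok), 5), collapse = ", "),
        if (sum(!ok) > 5) ", ..." else "", ")"))
    }
  }
  bad_rows(d$EVID %in% c(0L, 1L), "EVID must be 0 or 1")
  bad_rows(is.finite(d$TIME) & d$TIME >= 0, "TIME must be non-negative")
  dose <- d$EVID == 1L
  bad_rows(!dose | (is.finite(d$AMT) & d$AMT > 0), "dose rows need AMT > 0")
  bad_rows(dose | is.na(d$AMT), "observation rows must not carry AMT")
  obs <- d$EVID == 0L & d$MDV == 0L
  bad_rows(!obs | (is.finite(d$DV) & d$DV >= 0),
           "observation rows need DV >= 0")
  bad_rows(!obs | (is.finite(d$HCT) & d$HCT > 10 & d$HCT < 60),
           "observation rows need HCT in (10, 60)")
  mono <- unlist(tapply(d$TIME, factor(d$ID, levels = unique(d$ID)),
                        function(x) c(TRUE, diff(x) >= 0)), use.names = FALSE)
  bad_rows(mono, "TIME must be non-decreasing within subject")
  if (length(problems)) {
    stop("invalid PK dataset:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  d
}

#' Read / write a PK dataset
#'
#' Comma-separated text with a header row and dot decimals. Numeric values
#' are written with 9 significant digits, so a write/read round trip is
#' lossless at that precision; column order is fixed.
#'
#' @param path File path.
#' @return `read_pk_dataset`: a validated tibble. `write_pk_dataset`: `path`,
#'   invisibly.
#' @export
read_pk_dataset <- function(path) {
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                       na = c("", "NA", "."))
  validate_pk_dataset(d)
}

#' @rdname read_pk_dataset
#' @param data A validated PK dataset.
#' @export
write_pk_dataset <- function(data, path) {
  d <- validate_pk_dataset(data)
  fmt <- d
  num <- vapply(fmt, is.numeric, TRUE)
  fmt[num] <- lapply(fmt[num], function(x) {
    out <- formatC(x, digits = 9, format = "g")
    out[is.na(x)] <- NA_character_
    out
  })
  readr::write_csv(fmt, path, na = ".", progress = FALSE)
  invisible(path)
}
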