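#' Deduplicate case versions
#'
#' FAERS distributes every update to a safety report as a new PRIMARYID
#' under the same CASEID. Among reports sharing a CASEID the entry with the
#' most recent FDA_DT is retained; when FDA_DT also ties, the report with
#' the highest PRIMARYID is kept. PRIMARYIDs are compared numerically when
#' they parse as numbers and lexicographically otherwise; FDA_DT values
#' that do not parse as YYYYMMDD sort lowest and are never preferred over
#' a parseable date. Rows missing CASEID or PRIMARYID are dropped with a
#' counted warning.
#'
#' The operation is idempotent and invariant to input row order; output
#' rows keep the first-appearance order of their CASEIDs.
#'
#' @param demo data.frame/data.table of DEMO rows with columns `caseid`,
#'   `primaryid`, `fda_dt`.
#' @return data.table with exactly one row per CASEID; the attribute
#'   `dropped` counts rows discarded for missing identifiers.
#' @export
deduplicate_cases <- function(demo) {
  d <- as.data.table(demo)
  need <- c("caseid", "primaryid", "fda_dt")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    stop_config("demo rows lack column(s): %s", paste(missing_cols, collapse = ", "))
  }
  bad <- is.na(d$caseid) | !nzchar(d$caseid) |
    is.na(d$primaryid) | !nzchar(d$primaryid)
  n_bad <- sum(bad)
  if (n_bad) {
    warning(sprintf("dropping %d row(s) with missing CASEID or PRIMARYID", n_bad),
            call. = FALSE)
    d <- d[!bad]
  }
  if (nrow(d) == 0L) {
    out <- d
    data.table::setattr(out, "dropped", n_bad)
    return(out)
  }
  dt_key <- suppressWarnings(as.integer(d$fda_dt))
  dt_key[is.na(dt_key)] <- -1L
  pid_num <- suppressWarnings(as.numeric(d$primaryid))
  # numeric PRIMARYIDs compared by value via fixed-width zero padding;
  # non-numeric ones fall back to their lexicographic form
  pid_key <- ifelse(is.na(pid_num), d$primaryid,
                    sprintf("%024.0f", pid_num))
  ord <- order(d$caseid, dt_key, pid_key, method = "radix")
  cid_sorted <- d$caseid[ord]
  is_last <- c(cid_sorted[-1L] != cid_sorted[-length(cid_sorted)], TRUE)
  sel <- ord[is_last]  # best version per CASEID, in caseid-sorted order
  sel <- sel[match(unique(d$caseid), cid_sorted[is_last])]  # first-appearance order
  out <- d[sel]
  data.table::setattr(out, "dropped", n_bad)
  out
}

#' Remove cases flagged in quarterly deletion lists
#'
#' Deletion applies at CASEID granularity after deduplication, matching the
#' order in which FAERS deletion packages are meant to be applied. CASEIDs
#' in the deletion list that never occur in the data are counted but
#' otherwise ignored; surviving rows keep their order.
#'
#' @param cases deduplicated case rows (data.table with `caseid`).
#' @param dele DELE rows (data.frame with `caseid`), or `NULL`/empty.
#' @return data.table of surviving rows, with attributes `n_deleted` and
#'   `n_unknown_deletions`.
#' @export
apply_deletions <- function(cases, dele = NULL) {
  cases <- as.data.table(cases)
  del_ids <- unique(if (is.null(dele)) character(0) else as.character(dele$caseid))
  del_ids <- del_ids[nzchar(del_ids)]
  hit <- cases$caseid %in% del_ids
  out <- cases[!hit]
  data.table::setattr(out, "n_deleted", sum(hit))
  data.table::setattr(out, "n_unknown_deletions",
                      length(setdiff(del_ids, cases$caseid)))
  out
}

#' Restrict to healthcare-professional reports
#'
#' Keeps reports whose occupation code (OCCP_COD) is MD (physician),
#' PH (pharmacist) or OT (other health professional); consumer (CN),
#' lawyer (LW), other and missing codes are removed.
#'
#' @param cases case rows with an `occp_cod` column.
#' @return data.table of surviving rows with attribute `n_removed`.
#' @export
filter_hcp <- function(cases) {
  cases <- as.data.table(cases)
  keep <- cases$occp_cod %in% c("MD", "PH", "OT")
  out <- cases[keep]
  data.table::setattr(out, "n_removed", sum(!keep))
  out
}
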