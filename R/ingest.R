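REQUIRED_COLUMNS <- list(
  DEMO = c("primaryid", "caseid", "fda_dt"),
  DRUG = c("primaryid", "caseid", "drugname"),
  REAC = c("primaryid", "caseid", "pt"),
  OUTC = c("primaryid", "caseid", "outc_cod"),
  DELE = c("caseid"))

OPTIONAL_TABLES <- c("OUTC", "DELE", "THER", "INDI", "RPSR")

#' Read one quarter of FAERS-style "$"-delimited tables
#'
#' Looks for `DEMOyyQq.txt`, `DRUGyyQq.txt`, `REACyyQq.txt`, `OUTCyyQq.txt`
#' and `DELEyyQq.txt` in `dir`. DEMO, DRUG and REAC are required; OUTC and
#' DELE (and the accepted-but-ignored THER/INDI/RPSR) yield empty row sets
#' with a warning when absent. All fields are returned as character; a file
#' whose header lacks required columns raises an error naming the file and
#' the missing columns.
#'
#' @param dir directory containing the quarterly files.
#' @param quarter quarter label such as `"2023Q1"`.
#' @return named list of data.tables `DEMO`, `DRUG`, `REAC`, `OUTC`, `DELE`.
#' @export
read_quarter <- function(dir, quarter) {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter)) {
    stop_config("quarter label must look like 2023Q1, got '%s'", quarter)
  }
  stem <- paste0(substr(quarter, 3, 4), "Q", substr(quarter, 6, 6))
  out <- list()
  for (tbl in names(REQUIRED_COLUMNS)) {
    path <- file.path(dir, paste0(tbl, stem, ".txt"))
    if (!file.exists(path)) {
      if (tbl %in% OPTIONAL_TABLES) {
        warning(sprintf("%s file missing for %s; treating as empty", tbl, quarter),
                call. = FALSE)
        out[[tbl]] <- data.table::setnames(
          data.table::as.data.table(
            replicate(length(REQUIRED_COLUMNS[[tbl]]), character(0),
                      simplify = FALSE)),
          REQUIRED_COLUMNS[[tbl]])
        next
      }
      stop_config("required table %s missing for quarter %s (expected %s)",
                  tbl, quarter, path)
    }
    dt <- data.table::fread(path, sep = "$", colClasses = "character",
                            quote = "", header = TRUE, fill = TRUE)
    missing_cols <- setdiff(REQUIRED_COLUMNS[[tbl]], names(dt))
    if (length(missing_cols)) {
      stop_config("malformed header in %s: missing column(s) %s",
                  path, paste(missing_cols, collapse = ", "))
    }
    out[[tbl]] <- dt
  }
  out
}

#' Read and stack several quarters
#'
#' @param dir directory containing the quarterly files.
#' @param quarters character vector of quarter labels.
#' @return named list of stacked data.tables (`DEMO`, `DRUG`, `REAC`,
#'   `OUTC`, `DELE`), each with a `quarter` column recording provenance.
#' @export
read_quarters <- function(dir, quarters) {
  per_q <- lapply(quarters, function(q) {
    tabs <- read_quarter(dir, q)
    lapply(tabs, function(dt) {
      if (nrow(dt)) dt$quarter <- q else dt$quarter <- character(0)
      dt
    })
  })
  stats::setNames(lapply(names(REQUIRED_COLUMNS), function(tbl) {
    data.table::rbindlist(lapply(per_q, `[[`, tbl), fill = TRUE)
  }), names(REQUIRED_COLUMNS))
}
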