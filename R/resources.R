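#' Bundled shock preferred-term set
#'
#' The default term set is a surrogate for the licensed standardised MedDRA
#' query covering shock: the preferred terms Shock, Cardiogenic shock,
#' Septic shock, Anaphylactic shock, Hypovolemic shock, Distributive shock,
#' Circulatory collapse, Neurogenic shock, Obstructive shock and Toxic shock
#' syndrome. Real analyses against a licensed MedDRA/SMQ should replace it
#' with the full query via [read_term_set()].
#'
#' @return a `term_set` object (see [term_set()]).
#' @export
shock_term_set <- function() {
  read_term_set(pkg_resource("shock_pt_terms.txt"))
}

#' Build a preferred-term set
#'
#' Terms are matched case-insensitively after whitespace trimming; duplicate
#' terms (after case folding) are an error because they would make match
#' provenance ambiguous.
#'
#' @param terms character vector of MedDRA-style preferred terms.
#' @return an object of class `term_set`: the case-folded terms plus the
#'   original spellings.
#' @export
term_set <- function(terms) {
  terms <- trimws(terms)
  terms <- terms[nzchar(terms)]
  if (length(terms) == 0L) stop_config("term set must contain at least one term")
  folded <- toupper(terms)
  if (anyDuplicated(folded)) {
    stop_config("term set contains duplicate terms after case folding: %s",
                paste(unique(folded[duplicated(folded)]), collapse = ", "))
  }
  structure(list(terms = terms, folded = folded,
                 match_mode = "exact_case_insensitive"),
            class = "term_set")
}

#' Read a term set from a plain-text file (one preferred term per line)
#'
#' Blank lines and lines starting with `#` are ignored.
#'
#' @param path file path.
#' @return a `term_set` object.
#' @export
read_term_set <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  term_set(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", length(x$terms), " preferred terms (",
      x$match_mode, ")\n", sep = "")
  cat(paste0("  ", x$terms, collapse = "\n"), "\n")
  invisible(x)
}

#' Bundled demonstration drug universe
#'
#' One hundred common generic drug names, ordered by assumed prescribing
#' popularity (the simulator assigns Zipf exposure probabilities by row
#' order), each with an Anatomical Therapeutic Chemical (ATC) level-1 code.
#' The mapping is a small demonstration resource covering the synthetic drug
#' universe, not a licensed ATC extract.
#'
#' @return data.table with columns `drug` and `atc1`.
#' @export
default_drug_universe <- function() {
  data.table::fread(pkg_resource("drug_universe.tsv"), sep = "\t",
                    colClasses = "character")
}

#' Bundled demonstration ATC map (drug to level-1 class)
#'
#' @return named character vector mapping standardized drug name to ATC
#'   level-1 code.
#' @export
demo_atc_map <- function() {
  u <- default_drug_universe()
  stats::setNames(u$atc1, u$drug)
}

#' Bundled country-to-region map
#'
#' Two-column editable resource mapping ISO-2 country codes to the regions
#' used in the descriptive summary. Unknown countries map to
#' `"not_specified"`.
#'
#' @param path optional path to a replacement two-column (country, region)
#'   tab-delimited file.
#' @return named character vector country -> region.
#' @export
default_region_map <- function(path = NULL) {
  m <- data.table::fread(path %||% pkg_resource("region_map.tsv"),
                         sep = "\t", colClasses = "character")
  stats::setNames(m$region, m$country)
}

#' Bundled demonstration drug synonym map
#'
#' A small raw-name to standard-name map (e.g. METFORMIN HCL to METFORMIN)
#' standing in for a licensed drug dictionary; see [normalize_drug_name()].
#'
#' @return named character vector raw -> standard (keys already normalized).
#' @export
demo_synonym_map <- function() {
  m <- data.table::fread(pkg_resource("drug_synonyms.tsv"), sep = "\t",
                         colClasses = "character")
  stats::setNames(m$standard, m$raw)
}
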