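#' Read a peptide-level identification/quantification table
#'
#' Reads a TSV/CSV export of peptide observations into the canonical
#' observation table used downstream. Column names differ between search
#' engines, so the mapping is dialect-driven; two presets are shipped and a
#' custom mapping can be supplied.
#'
#' @param path path to a delimited text file with a header row.
#' @param dialect `"generic"`, `"spectromine"`, `"fragpipe"`, or a named
#'   character vector mapping canonical names (`sequence`, `accessions`,
#'   `run_id`, `intensity`, `q_value`, and optionally `is_heavy`) to the
#'   file's column names.
#' @param run_annotation optional data frame keyed by `run_id` with design
#'   coordinates (`assay`, `level`, `preparation`, `injection`); raw exports
#'   do not encode the validation design, so coordinates travel separately.
#' @param sep field separator (default tab).
#' @return A data frame with columns `sequence`, `accessions` (list column of
#'   accession vectors), `run_id`, `intensity`, `q_value`, `is_heavy`, plus
#'   design coordinates when `run_annotation` is given.
#' @export
read_peptide_table <- function(path, dialect = "generic",
                               run_annotation = NULL, sep = "\t") {
  dialects <- list(
    generic = c(sequence = "sequence", accessions = "accessions",
                run_id = "run_id", intensity = "intensity",
                q_value = "q_value", is_heavy = "is_heavy"),
    spectromine = c(sequence = "PEP.StrippedSequence",
                    accessions = "PG.ProteinAccessions",
                    run_id = "R.FileName", intensity = "PEP.Quantity",
                    q_value = "PEP.QValue", is_heavy = "PEP.IsHeavy"),
    fragpipe = c(sequence = "Peptide", accessions = "Mapped.Proteins",
                 run_id = "Spectrum.File", intensity = "Intensity",
                 q_value = "PeptideProphet.Probability",
                 is_heavy = "Is.Heavy"))
  map <- if (is.character(dialect) && length(dialect) == 1) {
    if (!dialect %in% names(dialects))
      stop("unknown dialect: ", dialect)
    dialects[[dialect]]
  } else dialect
  raw <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                           check.names = FALSE)
  required <- c("sequence", "accessions", "run_id", "intensity", "q_value")
  for (col in required) {
    if (!map[[col]] %in% names(raw))
      stop("peptide table is missing required column '", map[[col]],
           "' (", col, ")")
  }
  if (nrow(raw) == 0) {
    out <- data.frame(sequence = character(), run_id = character(),
                      intensity = numeric(), q_value = numeric(),
                      is_heavy = logical())
    out$accessions <- list()
    return(out[, c("sequence", "accessions", "run_id", "intensity",
                   "q_value", "is_heavy")])
  }
  intensity <- suppressWarnings(as.numeric(raw[[map[["intensity"]]]]))
  q_value <- suppressWarnings(as.numeric(raw[[map[["q_value"]]]]))
  bad <- which(is.na(intensity) | is.na(q_value))
  if (length(bad) > 0)
    stop("unparsable intensity/q-value at data line(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  if (any(intensity < 0)) stop("negative intensity values are not allowed")
  if (any(q_value < 0 | q_value > 1)) stop("q-values must lie in [0, 1]")
  sequence <- toupper(trimws(raw[[map[["sequence"]]]]))
  if (any(!nzchar(sequence))) stop("empty peptide sequence encountered")
  heavy_col <- map[["is_heavy"]]
  is_heavy <- if (!is.na(heavy_col) && heavy_col %in% names(raw))
    as.logical(raw[[heavy_col]]) else rep(FALSE, nrow(raw))
  out <- data.frame(sequence = sequence,
                    run_id = as.character(raw[[map[["run_id"]]]]),
                    intensity = intensity, q_value = q_value,
                    is_heavy = is_heavy, stringsAsFactors = FALSE)
  out$accessions <- strsplit(as.character(raw[[map[["accessions"]]]]),
                             "[;,] *")
  out <- out[, c("sequence", "accessions", "run_id", "intensity",
                 "q_value", "is_heavy")]
  if (!is.null(run_annotation)) {
    idx <- match(out$run_id, run_annotation$run_id)
    if (anyNA(idx))
      stop("run(s) missing from run annotation: ",
           paste(unique(out$run_id[is.na(idx)]), collapse = ", "))
    for (col in setdiff(names(run_annotation), "run_id"))
      out[[col]] <- run_annotation[[col]][idx]
  }
  out
}

#' Read a protein FASTA database
#'
#' Accessions are parsed from the first token of each header; the UniProt
#' `db|ACCESSION|NAME` convention is recognised and collapsed to the
#' accession. Sequences are uppercased.
#'
#' @param path path to a FASTA text file.
#' @return Named character vector mapping accession to sequence.
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- sub("[ \t].*$", "", names(aa))
  acc <- ifelse(grepl("^[a-z]{2}\\|", headers),
                vapply(strsplit(headers, "\\|"), `[`, character(1), 2),
                headers)
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(acc))
    stop("duplicate accession(s) in FASTA: ",
         paste(unique(acc[duplicated(acc)]), collapse = ", "))
  if (any(!nzchar(seqs)))
    stop("empty sequence for accession(s): ",
         paste(acc[!nzchar(seqs)], collapse = ", "))
  stats::setNames(seqs, acc)
}

#' Read a validation-design configuration file
#'
#' Accepts YAML or JSON with fields mirroring [validation_design()]:
#' `spike_ng`, `assay_levels`, `preparations`, `injections`, `beta`,
#' `acceptance_limit_aggregate`, `acceptance_limit_stratified`, `mab_mg`.
#' Missing fields fall back to the defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A `validation_design` object.
#' @export
read_design <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  args <- cfg[intersect(names(cfg), names(formals(validation_design)))]
  if (!is.null(args$assay_levels) && !is.list(args$assay_levels))
    args$assay_levels <- as.list(as.data.frame(args$assay_levels))
  do.call(validation_design, args)
}

#' Write and read result tables at full precision
#'
#' Result tables are written as TSV with maximal decimal precision so that a
#' write/read round trip reproduces every stored value exactly.
#'
#' @param x data frame to write.
#' @param path output path.
#' @return `write_result_table` returns `path` invisibly;
#'   `read_result_table` returns the data frame.
#' @export
write_result_table <- function(x, path) {
  df <- x
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) sprintf("%.17g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
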