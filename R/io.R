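## Readers reject rather than coerce: every failure names the offending
## row/column so a malformed file can be fixed at the source.

.readTable <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = c("NA", ""),
                    colClasses = "character")
}

.numericColumn <- function(df, col, path) {
  v <- df[[col]]
  out <- suppressWarnings(as.numeric(v))
  bad <- which(!is.na(v) & is.na(out))
  if (length(bad)) {
    stop("non-numeric cell in ", path, ": column '", col, "', row(s) ",
         paste(bad, collapse = ", "))
  }
  out
}

#' Read a gene copy-number table
#'
#' Expects a delimited file with a \code{sample_id} column and one
#' column per panel gene. Gene symbols are upper-cased; columns naming
#' genes outside the seven-gene chromosome-7 panel are dropped with a
#' warning; blank cells become missing genes. Duplicate sample ids and
#' non-numeric cells are errors.
#'
#' @param path File path.
#' @param sep Field delimiter (default tab).
#' @return data.frame with \code{sample_id} plus numeric gene columns.
#' @export
readGcnTable <- function(path, sep = "\t") {
  df <- .readTable(path, sep)
  if (!"sample_id" %in% names(df)) {
    stop("header must contain 'sample_id': ", path)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  genes <- setdiff(names(df), "sample_id")
  names(df)[match(genes, names(df))] <- toupper(genes)
  genes <- toupper(genes)
  unknown <- setdiff(genes, panelGenes())
  if (length(unknown)) {
    warning("ignoring unknown gene column(s): ",
            paste(unknown, collapse = ", "))
    df <- df[, c("sample_id", setdiff(genes, unknown)), drop = FALSE]
    genes <- setdiff(genes, unknown)
  }
  for (g in genes) df[[g]] <- .numericColumn(df, g, path)
  bad <- which(!is.na(df$MET) & df$MET <= 0)
  if ("MET" %in% genes && length(bad)) {
    stop("nonpositive MET copy number in ", path, ": row(s) ",
         paste(bad, collapse = ", "))
  }
  df
}

#' Write a gene copy-number table
#'
#' @param df data.frame as returned by [readGcnTable()].
#' @param path Output path.
#' @param sep Field delimiter (default tab).
#' @return Invisibly, \code{path}. Full floating precision is kept so a
#'   write-then-read round trip is exact.
#' @export
writeGcnTable <- function(df, path, sep = "\t") {
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a FISH observation table
#'
#' Accepts either the per-sample summary format (columns
#' \code{sample_id}, \code{mean_met}, \code{mean_cep7}) or the
#' long per-nucleus format (\code{sample_id}, \code{met_count},
#' \code{cep7_count}), which is collapsed through [fishFromNuclei()]
#' (at least 50 nuclei per sample; recomputed means override any stored
#' ones).
#'
#' @inheritParams readGcnTable
#' @return data.frame with columns \code{sample_id}, \code{mean_met},
#'   \code{mean_cep7}.
#' @export
readFishTable <- function(path, sep = "\t") {
  df <- .readTable(path, sep)
  if (all(c("met_count", "cep7_count") %in% names(df))) {
    nuc <- data.frame(sample_id = df$sample_id,
                      met_count = .numericColumn(df, "met_count", path),
                      cep7_count = .numericColumn(df, "cep7_count", path))
    out <- fishFromNuclei(nuc)
    return(out[, c("sample_id", "mean_met", "mean_cep7")])
  }
  need <- c("sample_id", "mean_met", "mean_cep7")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("FISH table lacks column(s): ", paste(miss, collapse = ", "),
         " in ", path)
  }
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop("duplicate sample_id in ", path, ": ",
         paste(unique(dup), collapse = ", "))
  }
  out <- data.frame(sample_id = df$sample_id,
                    mean_met = .numericColumn(df, "mean_met", path),
                    mean_cep7 = .numericColumn(df, "mean_cep7", path))
  if (any(is.na(out$mean_cep7)) || any(out$mean_cep7 <= 0)) {
    stop("mean_cep7 must be present and > 0 in ", path)
  }
  out
}

#' Read an annotated somatic-variant table
#'
#' @inheritParams readGcnTable
#' @return data.frame satisfying the [filterVariants()] column contract;
#'   out-of-range scores (e.g. VAF > 1) are rejected with the row index.
#' @export
readVariantTable <- function(path, sep = "\t") {
  df <- .readTable(path, sep)
  miss <- setdiff(.VARIANT_COLS, names(df))
  if (length(miss)) {
    stop("variant table lacks column(s): ", paste(miss, collapse = ", "),
         " in ", path)
  }
  for (col in c("vaf", "pop_freq", "sift", "polyphen2")) {
    df[[col]] <- .numericColumn(df, col, path)
  }
  .checkVariants(df)
  df
}

#' Write a ratio-gate model as JSON
#'
#' The file carries a \code{schema_version} field alongside the gates
#' and polysomy cutoff; thresholds are written at full precision so a
#' model round-trips exactly.
#'
#' @param model A [RatioGateModel-class].
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
writeModel <- function(model, path) {
  stopifnot(is(model, "RatioGateModel"))
  obj <- list(schema_version = 1L,
              gates = as.list(gateThresholds(model)),
              polysomy_gcn_threshold = polysomyThreshold(model))
  # I(17) significant digits: doubles survive the round trip bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a ratio-gate model from JSON
#'
#' Unknown top-level fields are rejected so silently mis-spelled
#' thresholds cannot slip through.
#'
#' @param path Path to a model JSON written by [writeModel()].
#' @return A [RatioGateModel-class].
#' @export
readModel <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  allowed <- c("schema_version", "gates", "polysomy_gcn_threshold")
  extra <- setdiff(names(obj), allowed)
  if (length(extra)) {
    stop("unknown field(s) in model file: ", paste(extra, collapse = ", "))
  }
  miss <- setdiff(c("gates", "polysomy_gcn_threshold"), names(obj))
  if (length(miss)) {
    stop("model file lacks field(s): ", paste(miss, collapse = ", "))
  }
  RatioGateModel(unlist(obj$gates), obj$polysomy_gcn_threshold)
}

## FNV-1a 32-bit over a string; cheap content fingerprint for reports.
.fnv1a <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h %% 2^31), b)  # keep in integer range
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}

#' Write an analysis report as JSON
#'
#' Wraps the payload with provenance metadata: package version,
#' timestamp, the seed in force (if any) and a content fingerprint.
#'
#' @param report Named list payload.
#' @param path Output path.
#' @param seed Optional integer seed recorded in the metadata.
#' @return Invisibly, \code{path}.
#' @export
writeReport <- function(report, path, seed = NULL) {
  payload_json <- jsonlite::toJSON(report, auto_unbox = TRUE, digits = NA,
                                   null = "null", na = "null")
  obj <- list(
    meta = list(tool = "MetGate",
                version = as.character(utils::packageVersion("MetGate")),
                timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
                seed = seed,
                content_hash = .fnv1a(as.character(payload_json))),
    report = report)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
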