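#' Read an expression matrix from TSV or GCT 1.2
#'
#' The TSV dialect is tab-separated UTF-8 with a header row of sample IDs
#' and gene symbols in the first column (header \code{"gene"}). GCT 1.2
#' files carry a \code{#1.2} version line, a dimensions line, and
#' \code{Name}/\code{Description} columns before the samples. Duplicate
#' gene symbols are preserved; collapsing is a separate, explicit step
#' (\code{\link{collapseDuplicateGenes}}).
#'
#' @param path file path.
#' @param format \code{"tsv"} or \code{"gct"}.
#' @param scale declared scale of the stored values (see
#'   \code{\link{ExpressionMatrix}}).
#' @return An \linkS4class{ExpressionMatrix}.
#' @export
readExpression <- function(path, format = c("tsv", "gct"),
                           scale = c("counts", "tpm", "logcpm",
                                     "quantile_normalized")) {
  format <- match.arg(format)
  scale <- match.arg(scale)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "gct") {
    lines <- readLines(path)
    if (length(lines) < 3L || !startsWith(lines[1L], "#1.2"))
      stop("malformed GCT header (line 1): expected '#1.2' in ", path)
    dims <- suppressWarnings(as.integer(strsplit(lines[2L], "\t")[[1L]]))
    if (length(dims) < 2L || anyNA(dims[1:2]))
      stop("malformed GCT dimensions row (line 2) in ", path)
    tab <- read.delim(text = paste(lines[-(1:2)], collapse = "\n"),
                      check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 3L)
      stop("malformed GCT column header (line 3) in ", path)
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -(1:2), drop = FALSE])
    if (nrow(vals) != dims[1L] || ncol(vals) != dims[2L])
      stop(sprintf("GCT dimensions row says %d x %d but body is %d x %d",
                   dims[1L], dims[2L], nrow(vals), ncol(vals)))
  } else {
    tab <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
    if (ncol(tab) < 2L)
      stop("malformed TSV header (line 1): need gene column + >=1 sample")
    genes <- as.character(tab[[1L]])
    vals <- as.matrix(tab[, -1L, drop = FALSE])
  }
  if (!is.numeric(vals)) {
    bad <- which(is.na(suppressWarnings(
      matrix(as.numeric(vals), nrow(vals)))) & !is.na(vals),
      arr.ind = TRUE)
    if (nrow(bad))
      stop(sprintf("non-numeric cell at data row %d, sample column %d",
                   bad[1L, 1L], bad[1L, 2L]))
    storage.mode(vals) <- "double"
  }
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)
    stop(sprintf("missing/NaN value at data row %d, sample column %d",
                 bad[1L, 1L], bad[1L, 2L]))
  }
  rownames(vals) <- genes
  message(sprintf("read %d genes x %d samples from %s",
                  nrow(vals), ncol(vals), path))
  ExpressionMatrix(vals, scale = scale)
}

#' Write an expression matrix to TSV or GCT 1.2
#'
#' @param x an \linkS4class{ExpressionMatrix}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"gct"}.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, format = c("tsv", "gct")) {
  format <- match.arg(format)
  m <- exprValues(x)
  if (format == "gct") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(m), ncol(m), sep = "\t")), con)
    tab <- data.frame(Name = rownames(m), Description = "na",
                      m, check.names = FALSE)
    suppressWarnings(write.table(tab, con, sep = "\t", quote = FALSE,
                                 row.names = FALSE))
  } else {
    tab <- data.frame(gene = rownames(m), m, check.names = FALSE)
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: \code{name <TAB> description <TAB> gene1 <TAB> ...}.
#' Symbols are uppercased and deduplicated within each set.
#'
#' @param path GMT file path.
#' @param name collection name (defaults to the file name).
#' @return A \linkS4class{GeneSetCollection}.
#' @export
readGmt <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  ln <- which(keep)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- vapply(fields, length, 1L)
  if (any(nf < 3L))
    stop(sprintf("GMT line %d has %d fields; need name, description, genes",
                 ln[which(nf < 3L)[1L]], nf[nf < 3L][1L]))
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  GeneSetCollection(name, sets)
}

#' Write a GeneSetCollection to GMT
#'
#' @param x a \linkS4class{GeneSetCollection}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGmt <- function(x, path) {
  sets <- geneSets(x)
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a plain-text gene signature (one symbol per line)
#'
#' @param path file path.
#' @param name signature name (defaults to the file name).
#' @return \code{readSignature}: a \linkS4class{GeneSignature}.
#' @export
readSignature <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  genes <- trimws(readLines(path))
  genes <- genes[nzchar(genes)]
  GeneSignature(name, genes)
}

#' @rdname readSignature
#' @param x a \linkS4class{GeneSignature}.
#' @export
writeSignature <- function(x, path) {
  writeLines(signatureGenes(x), path)
  invisible(path)
}

#' Construct or read a clinical table
#'
#' A clinical table is a validated data.frame with one row per sample per
#' endpoint: \code{sample_id}, \code{time_days} (non-negative, days from
#' diagnosis), \code{event} (1 = event observed, 0 = right-censored),
#' \code{endpoint} (\code{"DFI"}, \code{"OSv"} or \code{"PFS"}), and an
#' optional logical \code{metastatic_at_dx}.
#'
#' @param sample_id sample identifiers.
#' @param time_days non-negative times in days.
#' @param event 0/1 event indicators.
#' @param endpoint endpoint name per row (recycled if length 1).
#' @param metastatic_at_dx optional logical flag per row.
#' @return A validated clinical \code{data.frame}.
#' @export
clinicalTable <- function(sample_id, time_days, event, endpoint = "OSv",
                          metastatic_at_dx = NA) {
  df <- data.frame(sample_id = as.character(sample_id),
                   time_days = as.numeric(time_days),
                   event = as.integer(event),
                   endpoint = as.character(endpoint),
                   metastatic_at_dx = as.logical(metastatic_at_dx),
                   stringsAsFactors = FALSE)
  validateClinical(df)
}

validateClinical <- function(df) {
  req <- c("sample_id", "time_days", "event", "endpoint")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("clinical table missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df$time_days) || any(df$time_days < 0))
    stop("time_days must be non-negative and non-missing")
  if (!all(df$event %in% c(0L, 1L)))
    stop("event must be coded 1 = event observed, 0 = censored")
  if (!all(df$endpoint %in% c("DFI", "OSv", "PFS")))
    stop("endpoint must be one of DFI, OSv, PFS")
  if (anyDuplicated(df[, c("sample_id", "endpoint")]))
    stop("one row per sample per endpoint is required")
  df
}

#' @rdname clinicalTable
#' @param path TSV file with the clinical columns.
#' @export
readClinical <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"metastatic_at_dx" %in% names(df)) df$metastatic_at_dx <- NA
  validateClinical(df)
}

#' Harmonize a gene signature against a target gene universe
#'
#' Cross-species transfer matches genes by uppercased symbol: the mapped
#' signature is the intersection of the (uppercased) signature with the
#' (uppercased) target genes; unmatched symbols are reported, not dropped
#' silently. An empty intersection raises a warning, never an error - the
#' caller decides how to proceed.
#'
#' @param signature a \linkS4class{GeneSignature}.
#' @param targetGenes character vector of gene symbols available in the
#'   target cohort.
#' @return A list with \code{mapped} (a \linkS4class{GeneSignature}, or
#'   \code{NULL} if nothing matched) and \code{dropped} (character vector
#'   of unmatched symbols).
#' @examples
#' s <- GeneSignature("toy", c("tp53", "RB1", "CANINE1"))
#' harmonizeSymbols(s, c("TP53", "RB1", "MYC"))
#' @export
harmonizeSymbols <- function(signature, targetGenes) {
  stopifnot(is(signature, "GeneSignature"))
  target <- unique(toupper(as.character(targetGenes)))
  genes <- signatureGenes(signature)
  mapped <- genes[genes %in% target]
  dropped <- genes[!genes %in% target]
  if (length(mapped) == 0L) {
    warning("no signature genes found in target universe (",
            signatureName(signature), ")")
    return(list(mapped = NULL, dropped = dropped))
  }
  list(mapped = GeneSignature(signatureName(signature), mapped),
       dropped = dropped)
}

#' Write a workflow report bundle
#'
#' Serializes the components of a workflow report to TSV/JSON files in
#' \code{outDir} and writes \code{manifest.json} enumerating every file
#' alongside the parameters and RNG seed of the run. Reruns with the same
#' inputs produce byte-identical outputs.
#'
#' @param results a named list; data.frames become TSVs,
#'   \linkS4class{GeneSignature} objects become plain-text gene lists,
#'   \linkS4class{Bicluster} lists and other list-like components become
#'   JSON. Components named \code{params} / \code{seed} are echoed into
#'   the manifest rather than written as data files.
#' @param outDir output directory (created if needed).
#' @return The manifest, invisibly (also written as
#'   \code{manifest.json}).
#' @export
writeReportBundle <- function(results, outDir) {
  if (!dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  if (file.access(outDir, 2L) != 0L)
    stop("output directory not writable: ", outDir)
  files <- character(0)
  emit <- function(obj, nm) {
    if (is(obj, "GeneSignature")) {
      f <- file.path(outDir, paste0(nm, ".txt"))
      writeSignature(obj, f)
    } else if (is(obj, "ExpressionMatrix")) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      writeExpression(obj, f)
    } else if (is.data.frame(obj)) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      write.table(obj, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is(obj, "ClusteringResult")) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      lab <- clusterLabels(obj)
      df <- data.frame(sample_id = names(lab), cluster = unname(lab))
      pl <- prognosisLabels(obj)
      if (length(pl)) df$prognosis <- unname(pl[as.character(df$cluster)])
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is(obj, "Bicluster")) {
      f <- file.path(outDir, paste0(nm, ".json"))
      jsonlite::write_json(list(genes = biclusterGenes(obj),
                                samples = biclusterSamples(obj),
                                support = biclusterSupport(obj)),
                           f, auto_unbox = TRUE, digits = NA)
    } else if (is(obj, "TestResult")) {
      f <- file.path(outDir, paste0(nm, ".json"))
      jsonlite::write_json(list(statistic = unname(testStatistic(obj)),
                                name = obj@statisticName, df = obj@df,
                                p = testPValue(obj)),
                           f, auto_unbox = TRUE, digits = NA)
    } else if (is(obj, "KMCurve")) {
      f <- file.path(outDir, paste0(nm, ".tsv"))
      df <- data.frame(time = obj@time, n_risk = obj@nRisk,
                       n_event = obj@nEvent, surv = obj@surv)
      write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    } else if (is.list(obj) && length(obj) && !is.null(names(obj)) &&
               any(vapply(obj, function(e)
                 is(e, "Bicluster") || is(e, "GeneSignature") ||
                 is(e, "KMCurve") || is(e, "TestResult") ||
                 is(e, "ClusteringResult") || is.data.frame(e), TRUE))) {
      for (sub in names(obj)) emit(obj[[sub]], paste(nm, sub, sep = "_"))
      return(invisible(NULL))
    } else {
      f <- file.path(outDir, paste0(nm, ".json"))
      jsonlite::write_json(obj, f, auto_unbox = TRUE, digits = NA,
                           force = TRUE)
    }
    files <<- c(files, basename(f))
    invisible(NULL)
  }
  data_items <- setdiff(names(results), c("params", "seed"))
  for (nm in data_items) {
    if (!is.null(results[[nm]])) emit(results[[nm]], nm)
  }
  manifest <- list(files = as.list(sort(files)),
                   params = results$params,
                   seed = results$seed)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(manifest)
}
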