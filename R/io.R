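#' @importFrom Biostrings readDNAStringSet writeXStringSet
#' @importFrom rtracklayer import export
#' @importFrom jsonlite fromJSON
NULL

#' Read a DNA FASTA file with strict validation
#'
#' Wraps [Biostrings::readDNAStringSet()] with a pre-scan that reports
#' malformed headers and empty records by line number, upper-cases the
#' sequences, and restricts the alphabet to A/C/G/T/N.
#'
#' @param path path to a FASTA file.
#' @return A named [Biostrings::DNAStringSet], records in file order.
#' @export
readFastaDna <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("FASTA format error in ", path, ": empty file")
  hdr <- startsWith(lines, ">")
  if (!hdr[1])
    stop("FASTA format error in ", path, " at line 1: expected a '>' header")
  bad <- which(hdr & !grepl("^>\\S", lines))
  if (length(bad))
    stop("FASTA format error in ", path, " at line ", bad[1],
         ": header has no identifier")
  empty <- which(hdr & c(hdr[-1], TRUE))
  if (length(empty))
    stop("FASTA format error in ", path, " at line ", empty[1],
         ": record has an empty sequence")
  seqLines <- toupper(lines[!hdr])
  badChar <- grep("[^ACGTN]", seqLines)
  if (length(badChar))
    stop("FASTA format error in ", path, ": sequence line ",
         which(!hdr)[badChar[1]], " contains non-ACGTN characters")
  x <- readDNAStringSet(path)
  x <- DNAStringSet(toupper(as.character(x)))
  names(x) <- sub("\\s.*$", "", names(x))
  x
}

#' Write a DNA FASTA file
#'
#' @param seqs a named DNAStringSet or character vector.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFastaDna <- function(seqs, path) {
  if (!is(seqs, "DNAStringSet")) seqs <- DNAStringSet(toupper(seqs))
  writeXStringSet(seqs, path)
  invisible(path)
}

#' Read gene annotation from GFF3
#'
#' Validates coordinates and strands line by line (reporting the offending
#' line number), then imports through [rtracklayer::import()]. Gene
#' expression, when present, is read from the `expr` attribute. Coordinates
#' stay 1-based inclusive (GFF3 and GRanges share the convention).
#'
#' @param path path to a GFF3 file.
#' @param featureType feature types to keep (default `"gene"`; `NULL`
#'   keeps everything).
#' @return A [GenomicRanges::GRanges] with `gene_id` and, when present,
#'   numeric `expr` metadata columns. Overlapping genes on either strand
#'   are all retained; no merging is performed.
#' @export
readGenomeAnnotation <- function(path, featureType = "gene") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#") & nzchar(trimws(lines)))
  for (i in body) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 8)
      stop("GFF format error in ", path, " at line ", i, ": fewer than 8 columns")
    s <- suppressWarnings(as.integer(f[4])); e <- suppressWarnings(as.integer(f[5]))
    if (is.na(s) || is.na(e) || e < s)
      stop("GFF format error in ", path, " at line ", i, ": end < start")
    if (!f[7] %in% c("+", "-", "."))
      stop("GFF format error in ", path, " at line ", i, ": unknown strand '", f[7], "'")
  }
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(featureType) && "type" %in% names(mcols(gr)))
    gr <- gr[as.character(gr$type) %in% featureType]
  if (is.null(mcols(gr)$gene_id)) {
    id <- mcols(gr)$ID
    if (is.null(id)) id <- sprintf("feature%05d", seq_along(gr))
    mcols(gr)$gene_id <- as.character(id)
  }
  if (!is.null(mcols(gr)$expr)) mcols(gr)$expr <- as.numeric(mcols(gr)$expr)
  gr
}

#' Write gene annotation to GFF3
#'
#' @param gr a GRanges with `gene_id` (and optionally `expr`) metadata.
#' @param path output path.
#' @param source source column string.
#' @return `path`, invisibly.
#' @export
writeGenomeAnnotation <- function(gr, path, source = "crisprCrossTalk") {
  out <- gr
  mcols(out)$source <- source
  if (is.null(mcols(out)$type)) mcols(out)$type <- "gene"
  mcols(out)$ID <- mcols(out)$gene_id
  rtracklayer::export(out, path, format = "gff3")
  invisible(path)
}

CONFIG_KEYS <- c(
  seed = "seed", pam_convention = "pamConvention",
  pam_canonical = "pamCanonical", seed_region = "seedRegion",
  max_mismatches = "maxMismatches",
  min_trimmed_junction_len = "minTrimmedJunctionLen",
  repeat_anchor_len = "repeatAnchorLen", handle_len = "handleLen",
  sus_sample_size = "susSampleSize", sus_trials = "susTrials",
  structural_min_len = "structuralMinLen", fold_threshold = "foldThreshold",
  flank_identity_min = "flankIdentityMin",
  gene_overlap_frac = "geneOverlapFrac", orf_min_len = "orfMinLen",
  detection_limits = "detectionLimits")

#' Load a RunConfig from a JSON document
#'
#' Absent keys take package defaults (canonical GG PAM, seed region 1-8,
#' 8-nt handle, 5-nt anchor, 12-nt junction cutoff, 500 x 1000 sampling).
#' Unknown keys are a hard error, guarding against silent typos. The
#' resolved configuration is echoed via `message()`.
#'
#' @param path path to a JSON file with snake_case keys (`seed`,
#'   `pam_convention`, `pam_canonical`, `seed_region`, `max_mismatches`,
#'   `min_trimmed_junction_len`, `repeat_anchor_len`, `handle_len`,
#'   `sus_sample_size`, `sus_trials`, ...).
#' @param quiet suppress the config echo.
#' @return A [RunConfig-class].
#' @export
loadConfig <- function(path, quiet = FALSE) {
  doc <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (!is.list(doc) && length(doc) == 0) doc <- list()
  unknown <- setdiff(names(doc), names(CONFIG_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(doc$seed_region)) {
    sr <- as.integer(doc$seed_region)
    if (length(sr) != 2L || sr[1] < 1L)
      stop("seed_region must be a 1-based [first, last] pair with first >= 1")
  }
  if (!is.null(doc$detection_limits))
    doc$detection_limits <- unlist(doc$detection_limits)
  args <- stats::setNames(doc, CONFIG_KEYS[names(doc)])
  cfg <- do.call(runConfig, args)
  if (!quiet) {
    message("resolved config:")
    message(paste(utils::capture.output(show(cfg)), collapse = "\n"))
  }
  cfg
}

#' Fork a reproducible per-stage seed from the master seed
#'
#' One master seed drives the whole pipeline; each stochastic stage derives
#' its own 32-bit stream seed from `(seed, stage name)`, so that the order
#' in which stages run never changes any stage's draws.
#'
#' @param seed integer master seed.
#' @param stage stage name string.
#' @return An integer below 2^31 usable with [set.seed()].
#' @export
stageSeed <- function(seed, stage) {
  h <- 0
  for (cc in utf8ToInt(stage)) h <- (h * 131 + cc) %% 2147480009
  as.integer((abs(as.numeric(seed)) * 7919 + h) %% 2147480009)
}

#' Write a plain-text run log (version plus resolved configuration)
#'
#' @param config a RunConfig.
#' @param path output path.
#' @param extra optional named character vector of extra lines.
#' @return `path`, invisibly.
#' @export
writeRunLog <- function(config, path, extra = character(0)) {
  lines <- c(
    paste0("crisprCrossTalk ", as.character(utils::packageVersion("crisprCrossTalk"))),
    format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    utils::capture.output(show(config)),
    if (length(extra)) paste0(names(extra), ": ", extra))
  writeLines(lines, path)
  invisible(path)
}

# shared helpers ------------------------------------------------------------

revcompChr <- function(x) {
  as.character(reverseComplement(DNAStringSet(x)))
}

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Write a result table as TSV with a header row
#'
#' @param df a data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeResultTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
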