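#' @importFrom seqinr read.fasta write.fasta
#' @importFrom data.table fread fwrite
NULL

# Errors caused by bad user input (malformed files, invalid parameters) carry
# the class "mirtss_validation_error" so the command-line wrapper can map them
# to exit code 2 rather than 1.
abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("mirtss_validation_error", "error")))
}

FASTA_ALPHABET <- "ACGTNacgtn"

#' Read a soft-masked FASTA file
#'
#' Soft-masking (lowercase bases marking repeat-derived sequence) and `N`
#' characters are preserved exactly: all feature extraction in this package
#' distinguishes repeat from non-repeat bases by case.
#'
#' @param path Path to a FASTA file. Only the characters `A C G T N` (either
#'   case) are permitted in sequence lines.
#' @return A named character vector, one element per FASTA record.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "ACGTacgt"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  if (!file.exists(path)) abort_validation("FASTA file not found: %s", path)
  lines <- readLines(path)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) == 0L) return(stats::setNames(character(0), character(0)))
  if (!startsWith(lines[nonempty[1]], ">"))
    abort_validation("malformed FASTA: line %d does not start a record header",
                     nonempty[1])
  for (i in nonempty) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (nchar(trimws(sub("^>", "", ln))) == 0L)
        abort_validation("malformed FASTA header at line %d", i)
    } else if (grepl(sprintf("[^%s]", FASTA_ALPHABET), ln)) {
      abort_validation("illegal sequence character at line %d", i)
    }
  }
  recs <- seqinr::read.fasta(path, as.string = TRUE, forceDNAtolower = FALSE,
                             seqonly = FALSE)
  stats::setNames(vapply(recs, function(r) as.character(r)[1], character(1)),
                  names(recs))
}

#' Write sequences to FASTA, preserving soft-masking
#'
#' @param seqs Named character vector of sequences.
#' @param path Output file path.
#' @param line_width Bases per line.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, line_width = 60L) {
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    abort_validation("all sequences must be named")
  seqinr::write.fasta(as.list(unname(seqs)), names = names(seqs),
                      file.out = path, nbchar = line_width)
  invisible(path)
}

#' Read candidate TSS loci from a BED6 file
#'
#' Coordinates are BED-native 0-based half-open and are kept that way
#' internally. The strand column is mandatory: window extraction is
#' strand-aware.
#'
#' @param path Path to a 6-column BED file.
#' @return A data frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive), `name`, `score`, `strand`, in file order.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort_validation("BED file not found: %s", path)
  gr <- tryCatch(rtracklayer::import(path, format = "BED"),
                 error = function(e) abort_validation("malformed BED: %s",
                                                      conditionMessage(e)))
  strand <- as.character(BiocGenerics::strand(gr))
  if (any(strand == "*"))
    abort_validation("BED record(s) without strand: %s",
                     paste(which(strand == "*"), collapse = ", "))
  out <- data.frame(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = BiocGenerics::start(gr) - 1L,
    end    = BiocGenerics::end(gr),
    name   = if (is.null(gr$name)) sprintf("region%d", seq_along(gr)) else gr$name,
    score  = if (is.null(gr$score)) 0 else gr$score,
    strand = strand,
    stringsAsFactors = FALSE
  )
  bad <- which(out$start >= out$end)
  if (length(bad))
    abort_validation("empty or inverted interval(s) in BED records: %s",
                     paste(out$name[bad], collapse = ", "))
  out
}

#' Read one methylome track
#'
#' The file format is the four-column tab-separated layout used by
#' MethylomeDB-style brain methylation profiles: chromosome, 1-based
#' position, methylation probability, read coverage. Positions are shifted
#' to the package-internal 0-based convention on read.
#'
#' @param path Path to the track file (no header).
#' @param sample_id Identifier for the methylome; used to name the
#'   corresponding `MT_<sample_id>` feature.
#' @return A list with elements `sample_id` and `sites` (data frame with
#'   columns `chrom`, `pos` (0-based), `p`, `r`).
#' @export
read_methylation_track <- function(path, sample_id) {
  if (!file.exists(path)) abort_validation("track file not found: %s", path)
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "pos", "p", "r"),
                          colClasses = list(character = 1))
  if (nrow(dt)) {
    if (any(dt$p < 0 | dt$p > 1))
      abort_validation("methylation probability outside [0,1] in %s", path)
    if (any(dt$r < 0))
      abort_validation("negative read coverage in %s", path)
    dup <- duplicated(dt[, c("chrom", "pos")])
    if (any(dup))
      abort_validation("duplicate methylation site(s) at %s",
                       paste(sprintf("%s:%d", dt$chrom[dup], dt$pos[dup]),
                             collapse = ", "))
  }
  list(sample_id = sample_id,
       sites = data.frame(chrom = dt$chrom, pos = dt$pos - 1L,
                          p = dt$p, r = dt$r, stringsAsFactors = FALSE))
}

#' Reverse-complement a sequence, preserving soft-masking case
#'
#' @param x A single sequence string over `ACGTNacgtn`.
#' @return The reverse complement; lowercase bases stay lowercase.
#' @export
reverse_complement <- function(x) {
  comp <- chartr("ACGTNacgtn", "TGCANtgcan", x)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Extract a strand-aware fixed-length window around a TSS
#'
#' On the plus strand the window covers
#' `[tss - upstream, tss - upstream + total_len)`. On the minus strand the
#' genomic span is mirrored so that exactly `upstream` bases precede the TSS
#' in transcript orientation, and the reverse complement is returned
#' (soft-masking case is preserved base-wise). Windows that would run off
#' the chromosome are rejected, not clipped: a partial window would distort
#' every length-normalised feature.
#'
#' @param genome Named character vector of chromosome sequences
#'   (from [read_fasta()]).
#' @param tss A single locus: a list or one-row data frame with fields
#'   `chrom`, `start`, `end` (0-based half-open) and `strand`. The TSS base
#'   is `start` on the plus strand and `end - 1` on the minus strand.
#' @param upstream Bases upstream of the TSS (in transcript orientation)
#'   included in the window.
#' @param total_len Total window length in bp.
#' @return A list with elements `name`, `region` (genomic span of the
#'   window: `chrom`, `start`, `end`, `strand`), `seq` (the
#'   transcript-oriented window sequence) and `label` (`NA` until assigned).
#' @export
extract_window <- function(genome, tss, upstream = 500L, total_len = 1000L) {
  stopifnot(total_len > 0L, upstream >= 0L, upstream < total_len)
  chrom <- as.character(tss$chrom)
  if (!chrom %in% names(genome))
    abort_validation("chromosome %s not present in genome", chrom)
  strand <- as.character(tss$strand)
  if (!strand %in% c("+", "-"))
    abort_validation("strand must be '+' or '-', got '%s'", strand)
  tss_pos <- if (strand == "+") as.integer(tss$start) else as.integer(tss$end) - 1L
  if (strand == "+") {
    w_start <- tss_pos - as.integer(upstream)
  } else {
    w_start <- tss_pos - as.integer(total_len) + as.integer(upstream) + 1L
  }
  w_end <- w_start + as.integer(total_len)
  chrom_len <- nchar(genome[[chrom]])
  if (w_start < 0L || w_end > chrom_len)
    abort_validation("window [%d,%d) for locus %s exceeds chromosome %s (length %d)",
                     w_start, w_end,
                     if (!is.null(tss$name)) tss$name else "?", chrom, chrom_len)
  seq <- substr(genome[[chrom]], w_start + 1L, w_end)
  if (strand == "-") seq <- reverse_complement(seq)
  list(name = if (!is.null(tss$name)) as.character(tss$name) else NA_character_,
       region = list(chrom = chrom, start = w_start, end = w_end,
                     strand = strand),
       seq = seq,
       label = NA_integer_)
}
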