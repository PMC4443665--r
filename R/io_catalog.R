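#' Mutation catalogs
#'
#' A mutation catalog is a plain `data.frame` with one row per somatic
#' single-nucleotide variant and columns:
#'
#' * `sample` — sample identifier
#' * `chrom` — chromosome / contig name
#' * `pos` — 1-based position on the forward reference strand
#' * `ref`, `alt` — forward-strand reference and alternate base (`A,C,G,T`)
#' * `context5`, `context3` — forward-strand flanking bases (`NA` until
#'   [attach_context()] has run, or supplied in the input)
#' * `valid_context` — `FALSE` where the context could not be determined
#'   (sequence edge, `N` in the window, or a reference-base mismatch); such
#'   records are excluded from spectra
#' * `tx_strand` — transcript strand at the position: `"plus"`, `"minus"`,
#'   `"ambiguous"` (covered by transcripts on both strands) or `"none"`
#'   (`NA` until [annotate_tx_strand()] has run)
#'
#' Coordinates follow the MAF/VCF convention (1-based, forward strand);
#' interval inputs (transcripts, territory) follow the BED convention
#' (0-based half-open) and are converted at the boundary.
#'
#' @name catalog-format
NULL

CATALOG_COLS <- c("sample", "chrom", "pos", "ref", "alt",
                  "context5", "context3", "valid_context", "tx_strand")

new_catalog <- function(df) {
  for (col in setdiff(CATALOG_COLS, names(df))) {
    df[[col]] <- rep(if (col == "valid_context") NA else NA_character_,
                     nrow(df))
  }
  df <- df[, CATALOG_COLS]
  df$pos <- as.integer(df$pos)
  df$valid_context <- as.logical(df$valid_context)
  rownames(df) <- NULL
  df
}

#' Read a mutation catalog
#'
#' Reads per-sample somatic SNV records from a maf-lite TSV or a VCF. Only
#' single-nucleotide substitutions with `A,C,G,T` alleles are retained;
#' multi-allelic VCF records are split into one record per alternate allele.
#' The number of dropped non-SNV or non-ACGT records is reported via
#' `message()`.
#'
#' The maf-lite dialect is a tab-separated file with a header line and
#' columns `sample, chrom, pos, ref, alt`, optionally followed by
#' `context5, context3, tx_strand` (as written by [write_catalog()]).
#'
#' @param path Path to the file.
#' @param format `"maf-lite"` or `"vcf"`. VCF records take the sample name
#'   from `sample_id` if given, else from the single genotype column, else
#'   from the file name.
#' @param sample_id Optional sample name override for single-sample VCFs.
#' @return A catalog `data.frame` (see [catalog-format]). An empty catalog
#'   (zero rows) is returned with a warning for header-only input.
#' @export
read_catalog <- function(path, format = c("maf-lite", "vcf"),
                         sample_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  cat <- if (format == "maf-lite") read_maf_lite(path) else
    read_vcf_catalog(path, sample_id)
  if (nrow(cat) == 0) {
    warning("catalog is empty after filtering: ", path)
  }
  cat
}

read_maf_lite <- function(path) {
  df <- tryCatch(
    read.delim(path, stringsAsFactors = FALSE, colClasses = "character"),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e))
  )
  need <- c("sample", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("maf-lite header must contain columns: ", paste(need, collapse = ", "))
  }
  pos <- suppressWarnings(as.integer(df$pos))
  bad <- which(is.na(pos) & !is.na(df$pos))
  if (length(bad) > 0) {
    stop("unparseable pos at line ", bad[1] + 1L, " of ", path)
  }
  df$pos <- pos
  keep <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " non-SNV or non-ACGT record(s) dropped from ", path)
  }
  df <- df[keep, , drop = FALSE]
  if (!"valid_context" %in% names(df) && "context5" %in% names(df)) {
    df$valid_context <- df$context5 %in% BASES & df$context3 %in% BASES
  }
  new_catalog(df)
}

read_vcf_catalog <- function(path, sample_id = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (is.null(sample_id)) {
    gt_samples <- colnames(v@gt)
    gt_samples <- setdiff(gt_samples, "FORMAT")
    sample_id <- if (length(gt_samples) == 1) gt_samples else
      sub("\\.vcf(\\.gz)?$", "", basename(path))
  }
  if (nrow(fix) == 0) {
    return(new_catalog(data.frame(sample = character(), chrom = character(),
                                  pos = integer(), ref = character(),
                                  alt = character())))
  }
  # split multi-allelic ALT fields
  alts <- strsplit(fix$ALT, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  df <- data.frame(
    sample = sample_id,
    chrom = rep(fix$CHROM, n_alt),
    pos = rep(as.integer(fix$POS), n_alt),
    ref = rep(fix$REF, n_alt),
    alt = unlist(alts),
    stringsAsFactors = FALSE
  )
  keep <- df$ref %in% BASES & df$alt %in% BASES & df$ref != df$alt
  n_drop <- sum(!keep)
  if (n_drop > 0) {
    message(n_drop, " non-SNV or non-ACGT record(s) dropped from ", path)
  }
  new_catalog(df[keep, , drop = FALSE])
}

#' Write a mutation catalog as maf-lite TSV
#'
#' @param catalog A catalog `data.frame`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  write.table(catalog, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

load_reference <- function(reference) {
  if (is.character(reference)) {
    Biostrings::readDNAStringSet(reference)
  } else {
    stopifnot(methods::is(reference, "DNAStringSet"))
    reference
  }
}

#' Attach trinucleotide context from a reference sequence
#'
#' Fills `context5`/`context3` with the forward-strand reference bases at
#' `pos - 1` and `pos + 1`. Soft-masked (lower-case) bases are folded to
#' upper case. A record is flagged `valid_context = FALSE` (and excluded
#' from spectra downstream) when the position sits at a sequence edge, the
#' window contains a non-`ACGT` base, or the reference base disagrees with
#' the record's `ref` allele.
#'
#' @param catalog A catalog `data.frame`.
#' @param reference FASTA path or a `Biostrings::DNAStringSet`.
#' @return The catalog with context columns filled.
#' @export
attach_context <- function(catalog, reference) {
  ref <- load_reference(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  missing_chr <- setdiff(unique(catalog$chrom), names(ref))
  if (length(missing_chr) > 0) {
    stop("chromosome(s) absent from reference: ",
         paste(missing_chr, collapse = ", "))
  }
  n <- nrow(catalog)
  if (n == 0) return(catalog)
  lens <- Biostrings::width(ref)[match(catalog$chrom, names(ref))]
  if (any(catalog$pos < 1 | catalog$pos > lens)) {
    stop("mutation position outside reference sequence bounds")
  }
  at_edge <- catalog$pos < 2 | catalog$pos > lens - 1L
  c5 <- c3 <- rb <- rep(NA_character_, n)
  inb <- !at_edge
  if (any(inb)) {
    win <- Biostrings::subseq(
      ref[catalog$chrom[inb]],
      start = catalog$pos[inb] - 1L, width = 3L)
    win <- toupper(as.character(win))
    c5[inb] <- substr(win, 1, 1)
    rb[inb] <- substr(win, 2, 2)
    c3[inb] <- substr(win, 3, 3)
  }
  valid <- inb & c5 %in% BASES & c3 %in% BASES & rb %in% BASES &
    rb == catalog$ref
  n_mismatch <- sum(!is.na(rb) & rb %in% BASES & rb != catalog$ref)
  if (n_mismatch > 0) {
    message(n_mismatch, " record(s) flagged: reference base differs from ref allele")
  }
  if (any(at_edge)) {
    message(sum(at_edge), " record(s) flagged: position at sequence edge")
  }
  catalog$context5 <- c5
  catalog$context3 <- c3
  catalog$valid_context <- valid
  catalog
}

#' Read transcript annotation from BED6
#'
#' @param path BED file with at least 6 columns; the strand column (`+`/`-`)
#'   is required. Coordinates are 0-based half-open (BED convention).
#' @return A `GenomicRanges::GRanges` with strand set.
#' @export
read_transcripts <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  if (any(as.character(GenomicRanges::strand(gr)) == "*")) {
    stop("transcript BED must define strand (+/-) for every interval")
  }
  gr
}

#' Annotate transcription strand
#'
#' Sets `tx_strand` per mutation: `"plus"` or `"minus"` when the position is
#' covered only by transcripts of that strand, `"ambiguous"` when covered by
#' both, `"none"` when uncovered. Ambiguous positions are excluded from
#' strand-bias counting only, not from spectra.
#'
#' @param catalog A catalog `data.frame`.
#' @param transcripts A `GRanges` with strand (see [read_transcripts()]), or
#'   a BED6 path.
#' @return The catalog with `tx_strand` filled.
#' @export
annotate_tx_strand <- function(catalog, transcripts) {
  if (is.character(transcripts)) transcripts <- read_transcripts(transcripts)
  if (length(transcripts) == 0) stop("transcript annotation is empty")
  if (nrow(catalog) == 0) return(catalog)
  pos <- GenomicRanges::GRanges(
    catalog$chrom, IRanges::IRanges(catalog$pos, width = 1))
  st <- as.character(GenomicRanges::strand(transcripts))
  on_plus <- IRanges::overlapsAny(pos, transcripts[st == "+"],
                                  ignore.strand = TRUE)
  on_minus <- IRanges::overlapsAny(pos, transcripts[st == "-"],
                                   ignore.strand = TRUE)
  catalog$tx_strand <- ifelse(on_plus & on_minus, "ambiguous",
                       ifelse(on_plus, "plus",
                       ifelse(on_minus, "minus", "none")))
  catalog
}

fold_trinuc_counts <- function(counts64) {
  # counts64: named count of all 64 trinucleotides -> 32 pyrimidine-centred
  tri32 <- pyrimidine_trinucleotides()
  out <- setNames(numeric(32), tri32)
  for (t in tri32) {
    rc <- revcomp(t)
    out[t] <- counts64[t] + if (rc == t) 0 else counts64[rc]
  }
  out
}

#' Compute a trinucleotide opportunity vector
#'
#' Counts every 3-base window (at each offset) across the analyzed
#' territory, combining each trinucleotide with its reverse complement into
#' the 32 pyrimidine-centred classes. Territory intervals are merged before
#' counting so shared bases are not double-counted; windows containing `N`
#' are skipped. Lower-case (soft-masked) bases are folded to upper case.
#'
#' @param reference FASTA path or `DNAStringSet`.
#' @param territory Optional BED3 path or `GRanges` (0-based half-open when
#'   a path). `NULL` uses every full sequence.
#' @return Named numeric vector of 32 counts (an opportunity vector),
#'   ordered as [pyrimidine_trinucleotides()].
#' @export
compute_opportunities <- function(reference, territory = NULL) {
  ref <- load_reference(reference)
  names(ref) <- sub("\\s.*$", "", names(ref))
  if (is.null(territory)) {
    segs <- ref
  } else {
    gr <- if (is.character(territory))
      rtracklayer::import(territory, format = "BED") else territory
    gr <- GenomicRanges::reduce(gr, ignore.strand = TRUE)
    missing_chr <- setdiff(unique(as.character(GenomicRanges::seqnames(gr))),
                           names(ref))
    if (length(missing_chr) > 0) {
      stop("territory chromosome(s) absent from reference: ",
           paste(missing_chr, collapse = ", "))
    }
    lens <- Biostrings::width(ref)[match(as.character(GenomicRanges::seqnames(gr)),
                                         names(ref))]
    if (any(GenomicRanges::start(gr) < 1 | GenomicRanges::end(gr) > lens)) {
      stop("territory extends outside the reference sequence")
    }
    segs <- Biostrings::DNAStringSet(ref[as.character(GenomicRanges::seqnames(gr))],
                                     start = GenomicRanges::start(gr),
                                     end = GenomicRanges::end(gr))
  }
  segs <- Biostrings::DNAStringSet(toupper(as.character(segs)))
  counts64 <- colSums(Biostrings::trinucleotideFrequency(segs, step = 1))
  if (sum(counts64) == 0) {
    stop("territory contains no valid trinucleotide window")
  }
  fold_trinuc_counts(counts64)
}

#' Expand a 32-trinucleotide opportunity vector to 96 channels
#'
#' Each trinucleotide's count is replicated across its three alternate
#' alleles, so channel `c` receives the opportunity of its pyrimidine
#' context.
#'
#' @param opportunities Named 32-vector from [compute_opportunities()] or
#'   [read_opportunities()], or an already expanded 96-vector (returned
#'   unchanged).
#' @return Numeric vector of length 96 named by [channel_names()].
#' @export
expand_opportunities <- function(opportunities) {
  if (length(opportunities) == 96) {
    return(setNames(as.numeric(opportunities), channel_names()))
  }
  stopifnot(length(opportunities) == 32)
  tri32 <- pyrimidine_trinucleotides()
  if (!is.null(names(opportunities))) {
    opportunities <- opportunities[tri32]
  }
  ctx <- channel_contexts()
  tri_of_channel <- paste0(ctx$context5, ctx$ref, ctx$context3)
  setNames(as.numeric(opportunities)[match(tri_of_channel, tri32)],
           channel_names())
}

#' Read / write an opportunity table
#'
#' Two-column TSV (`trinucleotide`, `count`) over the 32 pyrimidine-centred
#' trinucleotides.
#'
#' @param path File path.
#' @return `read_opportunities()`: named numeric 32-vector.
#' @export
read_opportunities <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("trinucleotide", "count") %in% names(df)))
  tri32 <- pyrimidine_trinucleotides()
  if (!setequal(df$trinucleotide, tri32)) {
    stop("opportunity table must cover the 32 pyrimidine-centred trinucleotides")
  }
  setNames(df$count[match(tri32, df$trinucleotide)], tri32)
}

#' @rdname read_opportunities
#' @param opportunities Named 32-vector.
#' @export
write_opportunities <- function(opportunities, path) {
  write.table(
    data.frame(trinucleotide = names(opportunities),
               count = as.numeric(opportunities)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
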