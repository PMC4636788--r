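#' @import GenomicRanges
#' @import IRanges
#' @importFrom S4Vectors mcols mcols<- queryHits subjectHits
#' @importFrom GenomeInfoDb seqnames seqlevels seqlevels<- seqlengths seqlengths<-
#' @importFrom stats rlnorm rnorm runif rbinom setNames
#' @importFrom utils read.table write.table head tail
NULL

## ---------------------------------------------------------------------------
## Coordinate conventions
##
## All external interval formats (BED, narrowPeak, bedGraph, the annotation and
## LD-region tables) use 0-based half-open coordinates.  Internally everything
## is a GRanges (1-based closed); the conversion happens only in the readers
## and writers below, so a record round-trips exactly.
## ---------------------------------------------------------------------------

#' Build a GRanges from 0-based half-open coordinates
#'
#' The constructor used at every reader boundary. Validates the BED invariants
#' `0 <= start < end` before converting to the internal 1-based representation.
#'
#' @param chrom character vector of chromosome names (matched as exact strings,
#'   no "chr"-prefix normalisation).
#' @param start,end integer vectors, 0-based half-open.
#' @param strand one of `"+"`, `"-"`, `"."`; `"."` maps to `"*"`.
#' @return a `GRanges`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(is.na(start)) || any(is.na(end))) {
    stop("non-numeric interval coordinates")
  }
  bad <- which(start < 0 | end <= start)
  if (length(bad) > 0) {
    stop(sprintf("invalid interval at record %d: start=%s end=%s (need 0 <= start < end)",
                 bad[1], format(start[bad[1]], scientific = FALSE),
                 format(end[bad[1]], scientific = FALSE)))
  }
  strand <- rep(ifelse(strand == ".", "*", strand), length.out = length(start))
  GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1, end), strand = strand)
}

#' Pairwise interval overlap ("1 bp or more")
#'
#' Two intervals overlap iff they are on the same chromosome and share at least
#' one base. Book-ended (adjacent) intervals do not overlap.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return logical vector.
#' @export
interval_overlaps <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  as.character(seqnames(a)) == as.character(seqnames(b)) &
    start(a) <= end(b) & start(b) <= end(a)
}

#' Pairwise gap between intervals
#'
#' Gap in bp between two intervals on the same chromosome: 0 if they overlap
#' or are book-ended, otherwise the number of bases strictly between them.
#' `NA` if the intervals are on different chromosomes.
#'
#' @param a,b `GRanges` of equal length (or length 1, recycled).
#' @return numeric vector of distances (bp), `NA` across chromosomes.
#' @export
interval_distance <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep(a, length.out = n)
  b <- rep(b, length.out = n)
  d <- pmax(start(a) - end(b) - 1, start(b) - end(a) - 1, 0)
  d[as.character(seqnames(a)) != as.character(seqnames(b))] <- NA_real_
  d
}

#' Extend intervals symmetrically
#'
#' Widens each interval by `flank` bp on both sides, clipping at position 0.
#' Chromosome-end clipping is applied only when `chrom_sizes` is supplied.
#'
#' @param x a `GRanges`.
#' @param flank non-negative flank in bp (the element-assignment rule uses
#'   100,000).
#' @param chrom_sizes optional named vector of chromosome lengths.
#' @return a `GRanges` with the same metadata columns.
#' @export
extend_intervals <- function(x, flank, chrom_sizes = NULL) {
  if (length(flank) != 1 || is.na(flank) || flank < 0) {
    stop("flank must be a single non-negative number")
  }
  out <- x
  start(out) <- pmax(1, start(x) - flank)
  end(out) <- end(x) + flank
  if (!is.null(chrom_sizes)) {
    lim <- chrom_sizes[as.character(seqnames(out))]
    if (any(is.na(lim))) {
      stop("chromosome missing from chrom_sizes: ",
           paste(unique(as.character(seqnames(out))[is.na(lim)]), collapse = ", "))
    }
    end(out) <- pmin(end(out), lim)
  }
  out
}

sort_intervals <- function(x) {
  x[order(as.character(seqnames(x)), start(x), end(x))]
}

## ---------------------------------------------------------------------------
## Readers
## ---------------------------------------------------------------------------

read_delim_checked <- function(path, n_min_cols, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    return(list(lines = character(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf < n_min_cols)
  if (length(bad) > 0) {
    stop(sprintf("malformed %s line %d in %s: expected >= %d tab-separated fields, got %d",
                 what, bad[1], path, n_min_cols, nf[bad[1]]))
  }
  list(lines = lines, fields = fields)
}

num_field <- function(fields, i, path, what) {
  v <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", i)))
  bad <- which(is.na(v))
  if (length(bad) > 0) {
    stop(sprintf("malformed %s line %d in %s: field %d is not numeric",
                 what, bad[1], path, i))
  }
  v
}

chr_field <- function(fields, i) vapply(fields, `[[`, "", i)

check_intervals_by_line <- function(start, end, path, what) {
  bad <- which(!is.finite(start) | !is.finite(end) | start < 0 | end <= start)
  if (length(bad) > 0) {
    stop(sprintf("invalid interval at %s line %d in %s (need 0 <= start < end)",
                 what, bad[1], path))
  }
}

#' Read peak calls
#'
#' Supports the 10-column narrowPeak dialect (column 8 is -log10 p, converted
#' to `pvalue = 10^(-value)`) and a "bed6+pvalue" dialect whose 7th column is
#' the raw peak p-value. Intervals are 0-based half-open on disk.
#'
#' @param path file path.
#' @param format `"narrowPeak"` or `"bed6+pvalue"`.
#' @return a `GRanges` with metadata columns `name`, `pvalue` and `tags`
#'   (narrowPeak signalValue where available, otherwise `NA`).
#' @export
read_peaks <- function(path, format = c("narrowPeak", "bed6+pvalue")) {
  format <- match.arg(format)
  n_cols <- if (format == "narrowPeak") 10L else 7L
  parsed <- read_delim_checked(path, n_cols, format)
  if (length(parsed$lines) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$name <- character(0)
    mcols(gr)$pvalue <- numeric(0)
    mcols(gr)$tags <- numeric(0)
    return(gr)
  }
  f <- parsed$fields
  chrom <- chr_field(f, 1)
  start <- num_field(f, 2, path, format)
  end <- num_field(f, 3, path, format)
  check_intervals_by_line(start, end, path, format)
  if (format == "narrowPeak") {
    pvalue <- 10^(-num_field(f, 8, path, format))
    tags <- num_field(f, 7, path, format)
  } else {
    pvalue <- num_field(f, 7, path, format)
    tags <- rep(NA_real_, length(chrom))
  }
  bad <- which(pvalue <= 0 | pvalue > 1)
  if (length(bad) > 0) {
    stop(sprintf("invalid p-value at %s line %d in %s (need 0 < p <= 1)",
                 format, bad[1], path))
  }
  gr <- genomic_intervals(chrom, start, end, chr_field(f, 6))
  mcols(gr)$name <- chr_field(f, 4)
  mcols(gr)$pvalue <- pvalue
  mcols(gr)$tags <- tags
  gr
}

#' A signal track: genome-placed tags or per-bin counts
#'
#' @param data a `GRanges`: width-1 ranges for `mode = "tags"` (one tag per
#'   range), or bins with a numeric `count` metadata column for
#'   `mode = "bins"`.
#' @param library_size total mapped tags; defaults to the number of tags
#'   (or total bin count). Must be at least the total count represented.
#' @param mode `"tags"` or `"bins"`.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(data, library_size = NULL, mode = c("tags", "bins")) {
  mode <- match.arg(mode)
  total <- if (mode == "tags") length(data) else sum(mcols(data)$count)
  if (mode == "bins" && (is.null(mcols(data)$count) || any(mcols(data)$count < 0))) {
    stop("bin mode requires a non-negative 'count' metadata column")
  }
  if (is.null(library_size)) library_size <- max(total, 1)
  if (length(library_size) != 1 || is.na(library_size) || library_size <= 0) {
    stop("library_size must be a single positive number")
  }
  if (library_size < total) {
    stop("library_size is smaller than the total tag count represented")
  }
  structure(list(data = data, mode = mode, library_size = as.numeric(library_size)),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d %s, library size %s\n",
              length(x$data), x$mode, format(x$library_size, big.mark = ",")))
  invisible(x)
}

#' Count tags falling in query regions
#'
#' For tag tracks, the number of tag placements inside each region; for binned
#' tracks, the summed counts of bins overlapping each region.
#'
#' @param track a [signal_track()].
#' @param regions a `GRanges`.
#' @return numeric vector, one count per region.
#' @export
count_tags <- function(track, regions) {
  stopifnot(inherits(track, "signal_track"))
  if (track$mode == "tags") {
    GenomicRanges::countOverlaps(regions, track$data)
  } else {
    hits <- GenomicRanges::findOverlaps(regions, track$data)
    counts <- numeric(length(regions))
    if (length(hits) > 0) {
      agg <- tapply(mcols(track$data)$count[subjectHits(hits)], queryHits(hits), sum)
      counts[as.integer(names(agg))] <- as.numeric(agg)
    }
    counts
  }
}

#' Read a tag-position BED (one tag placement per line)
#'
#' @param path BED3+ file; each line is one tag (width-1 or wider intervals are
#'   reduced to their 5' start position).
#' @param library_size optional total mapped tags; defaults to the number of
#'   lines.
#' @return a [signal_track()] in tag mode.
#' @export
read_tag_bed <- function(path, library_size = NULL) {
  parsed <- read_delim_checked(path, 3L, "tag BED")
  if (length(parsed$lines) == 0) {
    return(signal_track(GenomicRanges::GRanges(), library_size = library_size %||% 1))
  }
  f <- parsed$fields
  chrom <- chr_field(f, 1)
  start <- num_field(f, 2, path, "tag BED")
  end <- num_field(f, 3, path, "tag BED")
  check_intervals_by_line(start, end, path, "tag BED")
  gr <- genomic_intervals(chrom, start, start + 1)
  signal_track(gr, library_size = library_size)
}

#' Read a bedGraph of binned signal
#'
#' @param path 4-column bedGraph (chrom, start, end, count).
#' @param library_size optional; defaults to the summed counts.
#' @return a [signal_track()] in bin mode.
#' @export
read_bedgraph <- function(path, library_size = NULL) {
  parsed <- read_delim_checked(path, 4L, "bedGraph")
  if (length(parsed$lines) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$count <- numeric(0)
    return(signal_track(gr, library_size = library_size %||% 1, mode = "bins"))
  }
  f <- parsed$fields
  chrom <- chr_field(f, 1)
  start <- num_field(f, 2, path, "bedGraph")
  end <- num_field(f, 3, path, "bedGraph")
  check_intervals_by_line(start, end, path, "bedGraph")
  gr <- genomic_intervals(chrom, start, end)
  mcols(gr)$count <- num_field(f, 4, path, "bedGraph")
  signal_track(gr, library_size = library_size, mode = "bins")
}

#' Read a two-column chromosome-sizes table
#'
#' @param path TSV with columns chrom, length.
#' @return named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  parsed <- read_delim_checked(path, 2L, "chrom sizes")
  if (length(parsed$lines) == 0) return(setNames(numeric(0), character(0)))
  f <- parsed$fields
  setNames(num_field(f, 2, path, "chrom sizes"), chr_field(f, 1))
}

#' Read a gene annotation table
#'
#' Expects a TSV with header `gene_id, biotype, chrom, start, end, strand`
#' (coordinates 0-based half-open; biotype one of coding, lncRNA, miRNA).
#' The strand-aware TSS is attached as a metadata column: the 5' base of the
#' body (`start` for `+`, `end - 1` in 0-based terms for `-`).
#'
#' @param path file path.
#' @return a `GRanges` with metadata columns `gene_id`, `biotype`, `tss`
#'   (1-based position of the TSS base).
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  need <- c("gene_id", "biotype", "chrom", "start", "end", "strand")
  if (!all(need %in% names(df))) {
    stop("gene annotation must have columns: ", paste(need, collapse = ", "))
  }
  bad <- which(!df$biotype %in% c("coding", "lncRNA", "miRNA"))
  if (length(bad) > 0) {
    stop(sprintf("unknown biotype '%s' at gene annotation line %d in %s",
                 df$biotype[bad[1]], bad[1] + 1L, path))
  }
  gr <- genomic_intervals(df$chrom, df$start, df$end, df$strand)
  mcols(gr)$gene_id <- df$gene_id
  mcols(gr)$biotype <- df$biotype
  mcols(gr)$tss <- ifelse(df$strand == "-", df$end, df$start + 1)
  gr
}

#' TSS positions of annotated genes as width-1 ranges
#'
#' @param genes a `GRanges` from [read_gene_annotation()] (or any GRanges with
#'   a `tss` metadata column; otherwise the strand-aware 5' end is used).
#' @return a `GRanges` of width-1 TSS positions carrying the gene metadata.
#' @export
gene_tss <- function(genes) {
  pos <- mcols(genes)$tss
  if (is.null(pos)) {
    pos <- ifelse(as.character(GenomicRanges::strand(genes)) == "-",
                  end(genes), start(genes))
  }
  out <- GenomicRanges::GRanges(seqnames(genes), IRanges::IRanges(pos, pos),
                                strand = GenomicRanges::strand(genes))
  mcols(out) <- mcols(genes)
  out
}

#' Read an expression table
#'
#' TSV with a `gene_id` column followed by one numeric column per condition
#' (normalized expression, all values >= 0).
#'
#' @param path file path.
#' @return a data.frame with `gene_id` and per-condition columns.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   quote = "", comment.char = "")
  if (names(df)[1] != "gene_id" || ncol(df) < 2) {
    stop("expression table must have a gene_id column followed by condition columns")
  }
  vals <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(vals) || any(is.na(vals)) || any(vals < 0)) {
    stop("expression values must be non-negative numbers")
  }
  if (anyDuplicated(df$gene_id)) stop("duplicated gene_id in expression table")
  df
}

#' Read eQTL linkage-disequilibrium regions
#'
#' BED whose name column (4) is the lead SNP identifier; an optional 5th
#' column carries the r-squared cutoff used upstream (default 0.8).
#'
#' @param path file path.
#' @return a `GRanges` with metadata columns `snp_id` and `r2_cutoff`.
#' @export
read_ld_regions <- function(path) {
  parsed <- read_delim_checked(path, 4L, "LD BED")
  if (length(parsed$lines) == 0) {
    gr <- GenomicRanges::GRanges()
    mcols(gr)$snp_id <- character(0)
    mcols(gr)$r2_cutoff <- numeric(0)
    return(gr)
  }
  f <- parsed$fields
  start <- num_field(f, 2, path, "LD BED")
  end <- num_field(f, 3, path, "LD BED")
  check_intervals_by_line(start, end, path, "LD BED")
  gr <- genomic_intervals(chr_field(f, 1), start, end)
  mcols(gr)$snp_id <- chr_field(f, 4)
  r2 <- if (all(lengths(f) >= 5)) num_field(f, 5, path, "LD BED") else rep(0.8, length(gr))
  if (any(r2 <= 0 | r2 > 1)) stop("r2_cutoff must be in (0, 1]")
  mcols(gr)$r2_cutoff <- r2
  gr
}

## ---------------------------------------------------------------------------
## Writers
## ---------------------------------------------------------------------------

#' Write intervals as BED
#'
#' Deterministic output: records sorted by (chrom, start, end), tab-separated,
#' 0-based half-open, scores formatted with 6 decimals.
#'
#' @param x a `GRanges`.
#' @param path output path.
#' @param name optional character vector (or metadata column name) for BED
#'   column 4.
#' @param score optional numeric vector (or metadata column name) for column 5.
#' @return invisibly, the path.
#' @export
write_bed <- function(x, path, name = NULL, score = NULL) {
  pick <- function(v) {
    if (is.character(v) && length(v) == 1 && !is.null(mcols(x)[[v]])) mcols(x)[[v]] else v
  }
  name <- pick(name)
  score <- pick(score)
  o <- order(as.character(seqnames(x)), start(x), end(x))
  cols <- list(as.character(seqnames(x))[o],
               format(start(x)[o] - 1, scientific = FALSE, trim = TRUE),
               format(end(x)[o], scientific = FALSE, trim = TRUE))
  if (!is.null(name)) cols <- c(cols, list(as.character(name)[o]))
  if (!is.null(score)) {
    if (is.null(name)) cols <- c(cols, list(rep(".", length(x))))
    cols <- c(cols, list(sprintf("%.6f", as.numeric(score)[o])))
  }
  lines <- do.call(paste, c(cols, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write a data.frame as a deterministic TSV
#'
#' @param df data.frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, logical(1))
  for (j in which(num)) {
    df[[j]] <- ifelse(is.na(df[[j]]), "NA",
                      ifelse(df[[j]] == round(df[[j]]) & abs(df[[j]]) < 1e15,
                             format(df[[j]], scientific = FALSE, trim = TRUE),
                             sprintf("%.6f", df[[j]])))
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, eol = "\n")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round a proportion to a percentage, halves up
#'
#' Report-style percentage used throughout: `percent_half_up(550, 1019)` is 54.
#'
#' @param num,den numerator and denominator counts.
#' @param digits decimal places (default 0).
#' @return numeric percentage.
#' @export
percent_half_up <- function(num, den, digits = 0) {
  if (any(den <= 0)) stop("denominator must be positive")
  p <- 100 * num / den
  floor(p * 10^digits + 0.5) / 10^digits
}
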