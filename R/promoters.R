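#' Construct a promoter set
#'
#' A promoter set is a tibble with one row per gene and columns `gene` and
#' `sequence`, carrying the shared promoter geometry as attributes. Every
#' sequence spans positions \eqn{-M..+N} relative to the transcription start
#' site (TSS), where `M = upstream` and `N = downstream`; position 0 is the
#' TSS base itself, so each sequence has length `M + N + 1`. Sequences are
#' stored on the promoter sense strand, reading 5' to 3' through the TSS.
#' Masked positions (repeats, transposons, or unknown bases) are lowercase
#' or `N`; only unmasked ("free") positions take part in motif scanning and
#' in the position-bias background.
#'
#' @param gene Character vector of gene identifiers (unique).
#' @param sequence Character vector of promoter sequences, same length as
#'   `gene`; alphabet `A,C,G,T,N` in either case. Lowercase and `N` mark
#'   masked positions.
#' @param upstream Bases upstream of the TSS (M, non-negative).
#' @param downstream Bases downstream of the TSS (N, non-negative).
#' @return A tibble of class `promoter_set` with attributes `upstream` and
#'   `downstream`.
#' @examples
#' promoter_set(c("g1", "g2"), c("ACGTA", "ccGTA"), upstream = 2, downstream = 2)
#' @export
promoter_set <- function(gene, sequence, upstream, downstream) {
  stopifnot(length(gene) == length(sequence))
  check_geometry(upstream, downstream)
  if (anyDuplicated(gene)) {
    stop("duplicated gene ids: ", paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  len <- upstream + downstream + 1L
  bad <- nchar(sequence) != len
  if (any(bad)) {
    stop("promoter length must be upstream + downstream + 1 = ", len,
         "; offending genes: ", paste(gene[bad], collapse = ", "))
  }
  out <- tibble::tibble(gene = as.character(gene), sequence = as.character(sequence))
  attr(out, "upstream") <- as.integer(upstream)
  attr(out, "downstream") <- as.integer(downstream)
  class(out) <- c("promoter_set", class(out))
  out
}

check_geometry <- function(upstream, downstream) {
  if (length(upstream) != 1 || length(downstream) != 1 ||
      is.na(upstream) || is.na(downstream) || upstream < 0 || downstream < 0) {
    stop("upstream and downstream must be single non-negative lengths (bp)")
  }
  if (upstream + downstream < 1) stop("promoter must span at least 2 positions")
  invisible(TRUE)
}

#' @export
`[.promoter_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "upstream") <- attr(x, "upstream")
    attr(out, "downstream") <- attr(x, "downstream")
    class(out) <- unique(c("promoter_set", class(out)))
  }
  out
}

#' @export
print.promoter_set <- function(x, ...) {
  cat(sprintf("# A promoter set: %d promoters, -%d..+%d relative to TSS\n",
              nrow(x), promoter_upstream(x), promoter_downstream(x)))
  NextMethod()
}

#' Promoter geometry accessors
#'
#' @param promoters A [promoter_set()].
#' @return The upstream extent M, downstream extent N (bp), or the vector of
#'   TSS-relative positions `-M..N`.
#' @export
promoter_upstream <- function(promoters) attr(promoters, "upstream")

#' @rdname promoter_upstream
#' @export
promoter_downstream <- function(promoters) attr(promoters, "downstream")

#' @rdname promoter_upstream
#' @export
promoter_positions <- function(promoters) {
  seq.int(-promoter_upstream(promoters), promoter_downstream(promoters))
}

# logical matrix (positions x genes): TRUE where the base is free (unmasked).
# Masked = lowercase or N, following the RepeatMasker soft/hard-mask convention.
free_matrix <- function(promoters) {
  chars <- strsplit(promoters$sequence, "", fixed = TRUE)
  m <- vapply(chars, function(s) s %in% c("A", "C", "G", "T"),
              logical(nchar(promoters$sequence[1])))
  m <- matrix(m, ncol = nrow(promoters),
              dimnames = list(NULL, promoters$gene))
  m
}

#' Per-position free-base counts for a promoter group
#'
#' Counts, for every TSS-relative position i, how many promoters in `group`
#' are unmasked at i. This is the `k_i` vector of the position-bias
#' background.
#'
#' @param promoters A [promoter_set()].
#' @param group Character vector of gene ids; default all genes in the set.
#' @return Integer vector indexed by position `-M..N`.
#' @keywords internal
free_counts <- function(promoters, group = NULL) {
  if (!is.null(group)) {
    missing <- setdiff(group, promoters$gene)
    if (length(missing)) stop("genes not in promoter set: ", paste(missing, collapse = ", "))
    promoters <- promoters[promoters$gene %in% group, , drop = FALSE]
  }
  if (nrow(promoters) == 0) stop("empty promoter group")
  rowSums(free_matrix(promoters))
}

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                    a = "t", c = "g", g = "c", t = "a", n = "n")

revcomp_chr <- function(s) {
  vapply(strsplit(s, "", fixed = TRUE), function(ch) {
    paste(rev(unname(DNA_COMPLEMENT[ch])), collapse = "")
  }, character(1))
}

#' Read and write promoter sets as masked FASTA
#'
#' Masked positions are written lowercase (soft-masking); hard-masked `N`
#' bases survive a round trip unchanged. The geometry is recorded on each
#' header line as `gene upstream=M downstream=N` and recovered on read (or
#' supplied explicitly).
#'
#' @param promoters A [promoter_set()].
#' @param path File path.
#' @param upstream,downstream Geometry override when the headers carry none.
#' @return `write_promoters_fasta()` returns `path` invisibly;
#'   `read_promoters_fasta()` returns a [promoter_set()].
#' @export
write_promoters_fasta <- function(promoters, path) {
  header <- sprintf("%s upstream=%d downstream=%d", promoters$gene,
                    promoter_upstream(promoters), promoter_downstream(promoters))
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::BStringSet(promoters$sequence)
    names(x) <- header
    Biostrings::writeXStringSet(x, path)
  } else {
    writeLines(paste0(">", header, "\n", promoters$sequence), path)
  }
  invisible(path)
}

#' @rdname write_promoters_fasta
#' @export
read_promoters_fasta <- function(path, upstream = NULL, downstream = NULL) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    x <- Biostrings::readBStringSet(path)
    headers <- names(x)
    seqs <- as.character(x)
  } else {
    lines <- readLines(path)
    idx <- grepl("^>", lines)
    headers <- sub("^>", "", lines[idx])
    seqs <- vapply(split(lines[!idx], cumsum(idx)[!idx]), paste, character(1), collapse = "")
  }
  gene <- sub("\\s.*$", "", headers)
  up <- suppressWarnings(as.integer(sub(".*upstream=(\\d+).*", "\\1", headers)))
  dn <- suppressWarnings(as.integer(sub(".*downstream=(\\d+).*", "\\1", headers)))
  if (is.null(upstream)) upstream <- up[1]
  if (is.null(downstream)) downstream <- dn[1]
  if (is.na(upstream) || is.na(downstream)) {
    stop("promoter geometry not in FASTA headers; pass upstream/downstream")
  }
  promoter_set(gene, unname(seqs), upstream, downstream)
}

#' Extract promoter sequences from a genome
#'
#' Cuts the window \eqn{[-M, +N]} around each gene's TSS out of a genome and
#' orients it on the promoter sense strand: minus-strand promoters are
#' reverse-complemented so position \eqn{-M..+N} always reads 5' to 3'
#' toward and through the TSS. Genomic intervals are 0-based half-open; for
#' a plus-strand TSS at genomic coordinate t the window is
#' `[t - upstream, t + downstream + 1)`, for a minus-strand TSS
#' `[t - downstream, t + upstream + 1)`. Soft-masked (lowercase) and `N`
#' bases in the source are kept masked. Windows running off a chromosome end
#' are padded with `N` and flagged with a warning.
#'
#' @param genome A named character vector of chromosome sequences, a
#'   `Biostrings::DNAStringSet`, or the path to a FASTA file.
#' @param genes A data frame with columns `chrom`, `tss` (0-based genomic
#'   coordinate of the TSS base), `strand` (`+`/`-`), `gene`; or the path to
#'   a BED6 / GTF file (see [read_gene_models()]).
#' @param upstream,downstream Promoter geometry in bp.
#' @return A [promoter_set()].
#' @export
extract_promoters <- function(genome, genes, upstream = 2500, downstream = 200) {
  check_geometry(upstream, downstream)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome)) {
    if (requireNamespace("Biostrings", quietly = TRUE)) {
      gg <- Biostrings::readBStringSet(genome)
      genome <- structure(as.character(gg), names = sub("\\s.*$", "", names(gg)))
    } else {
      stop("reading a genome FASTA requires the Biostrings package")
    }
  } else if (inherits(genome, "XStringSet")) {
    genome <- structure(as.character(genome), names = sub("\\s.*$", "", names(genome)))
  }
  if (is.character(genes) && length(genes) == 1) genes <- read_gene_models(genes)
  genes <- tibble::as_tibble(genes)
  required <- c("chrom", "tss", "strand", "gene")
  if (!all(required %in% names(genes))) {
    stop("gene models need columns: ", paste(required, collapse = ", "))
  }
  if (nrow(genes) == 0) stop("zero genes parsed from gene models")
  unknown <- setdiff(unique(genes$chrom), names(genome))
  if (length(unknown)) {
    stop("chromosomes absent from genome: ", paste(unknown, collapse = ", "),
         " (genes: ", paste(genes$gene[genes$chrom %in% unknown], collapse = ", "), ")")
  }
  truncated <- character(0)
  seqs <- vapply(seq_len(nrow(genes)), function(r) {
    chrom <- genome[[genes$chrom[r]]]
    t <- genes$tss[r]
    if (genes$strand[r] == "-") {
      start0 <- t - downstream
      end0 <- t + upstream + 1
    } else {
      start0 <- t - upstream
      end0 <- t + downstream + 1
    }
    lo <- max(start0, 0)
    hi <- min(end0, nchar(chrom))
    if (lo > start0 || hi < end0) truncated <<- c(truncated, genes$gene[r])
    core <- if (hi > lo) substr(chrom, lo + 1, hi) else ""
    s <- paste0(strrep("N", lo - start0), core, strrep("N", end0 - hi))
    if (genes$strand[r] == "-") revcomp_chr(s) else s
  }, character(1))
  if (length(truncated)) {
    warning("promoters truncated at chromosome ends (N-padded): ",
            paste(truncated, collapse = ", "))
  }
  promoter_set(genes$gene, seqs, upstream, downstream)
}

#' Read gene models from BED6 or GTF
#'
#' Returns one TSS record per gene: the `thickStart`-free BED6 start (plus
#' strand) or end-1 (minus strand), or the GTF `gene`/`transcript` feature's
#' 5' end. GTF coordinates are converted from 1-based inclusive to the
#' 0-based TSS coordinate used by [extract_promoters()].
#'
#' @param path BED6 (`chrom start end name score strand`) or GTF file; format
#'   chosen by extension (`.bed` vs `.gtf`/`.gff`).
#' @return Tibble with columns `chrom`, `tss`, `strand`, `gene`.
#' @export
read_gene_models <- function(path) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    bed <- utils::read.table(path, sep = "\t", header = FALSE,
                             col.names = c("chrom", "start", "end", "name", "score", "strand"),
                             colClasses = c("character", "integer", "integer",
                                            "character", "character", "character"))
    tss <- ifelse(bed$strand == "-", bed$end - 1L, bed$start)
    out <- tibble::tibble(chrom = bed$chrom, tss = tss, strand = bed$strand, gene = bed$name)
  } else {
    gtf <- utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                             quote = "", stringsAsFactors = FALSE)
    names(gtf) <- c("chrom", "source", "feature", "start", "end",
                    "score", "strand", "frame", "attributes")
    gtf <- gtf[gtf$feature %in% c("gene", "transcript"), , drop = FALSE]
    if (any(gtf$feature == "gene")) gtf <- gtf[gtf$feature == "gene", , drop = FALSE]
    gid <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", gtf$attributes)
    tss <- ifelse(gtf$strand == "-", gtf$end - 1L, gtf$start - 1L)
    out <- tibble::tibble(chrom = gtf$chrom, tss = as.integer(tss),
                          strand = gtf$strand, gene = gid)
  }
  if (nrow(out) == 0) stop("zero genes parsed from ", path)
  out
}
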