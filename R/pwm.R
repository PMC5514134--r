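#' Build a position weight matrix from a count matrix
#'
#' Converts a position frequency matrix (counts) into per-column base
#' probabilities (after adding a pseudocount) and into log-odds scores in
#' bits against a background base composition. Scores of a sequence window
#' are sums of per-column log-odds, the POSSUM-style additive scoring used
#' throughout the package.
#'
#' @param counts 4 x w numeric matrix of base counts, rows A, C, G, T.
#' @param pseudocount Added to every cell before normalisation (default 1).
#' @param background Length-4 base probabilities (A, C, G, T), summing to 1.
#'   Default uniform 0.25 — promoter scans may instead pass the observed
#'   promoter composition.
#' @param id Optional motif identifier carried through to hits.
#' @return An object of class `pwm`: a list with elements `id`, `width`,
#'   `prob` (4 x w), `log_odds` (4 x w, bits), `background`, `consensus`.
#' @examples
#' pwm_from_consensus("CCAAT")
#' @export
pwm_from_counts <- function(counts, pseudocount = 1, background = rep(0.25, 4), id = "motif") {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("counts must have 4 rows (A, C, G, T)")
  if (any(!is.finite(counts)) || any(counts < 0)) stop("counts must be non-negative numbers")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6) {
    stop("background must be 4 positive probabilities summing to 1")
  }
  cs <- colSums(counts) + 4 * pseudocount
  if (any(cs == 0)) stop("column sums of zero in the count matrix")
  prob <- sweep(counts + pseudocount, 2, cs, "/")
  rownames(prob) <- c("A", "C", "G", "T")
  background <- stats::setNames(as.numeric(background), c("A", "C", "G", "T"))
  log_odds <- log2(prob / background)    # -Inf where prob is 0: exact matches only
  consensus <- paste(rownames(prob)[apply(prob, 2, which.max)], collapse = "")
  structure(list(id = id, width = ncol(prob), prob = prob,
                 log_odds = log_odds, background = background,
                 consensus = consensus),
            class = "pwm")
}

#' @rdname pwm_from_counts
#' @param consensus A string over A/C/G/T; each position becomes a count
#'   column with all mass on the consensus base, giving a PWM that matches
#'   the consensus word exactly and scores every other word `-Inf`.
#' @export
pwm_from_consensus <- function(consensus, background = rep(0.25, 4), id = consensus) {
  bases <- strsplit(toupper(consensus), "", fixed = TRUE)[[1]]
  if (!all(bases %in% c("A", "C", "G", "T"))) stop("consensus must be over A/C/G/T")
  counts <- vapply(bases, function(b) 100 * (c("A", "C", "G", "T") == b), numeric(4))
  pwm_from_counts(counts, pseudocount = 0, background = background, id = id)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm %s> width %d, consensus %s, max score %.2f bits\n",
              x$id, x$width, x$consensus, sum(apply(x$log_odds, 2, max))))
  invisible(x)
}

# reverse complement of a PWM: reverse columns, swap A<->T and C<->G rows
pwm_revcomp <- function(pwm) {
  flip <- function(m) m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  out <- pwm
  p <- flip(pwm$prob); rownames(p) <- c("A", "C", "G", "T")
  lo <- flip(pwm$log_odds); rownames(lo) <- c("A", "C", "G", "T")
  out$prob <- p
  out$log_odds <- lo
  out$consensus <- revcomp_chr(pwm$consensus)
  out
}

#' Read a motif from a JASPAR PFM file
#'
#' Accepts the JASPAR 2016 text layout
#' (`>MA0079.3 SP1` header followed by four rows `A [ 12 3 ... ]`) as well
#' as bare 4-row count matrices. Multi-motif files are supported; select one
#' with `id`.
#'
#' @param path JASPAR PFM text file.
#' @param id Motif identifier to pick when the file holds several
#'   (default: the first motif).
#' @inheritParams pwm_from_counts
#' @return A [pwm_from_counts()] object.
#' @export
load_jaspar_pwm <- function(path, id = NULL, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  parse_block <- function(block, name) {
    rows <- lapply(block, function(l) {
      l <- sub("^[ACGTacgt][ :|]*", "", l)
      l <- gsub("[][]", " ", l)
      v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
      if (any(is.na(v))) stop("non-numeric counts in PFM block for ", name)
      v
    })
    if (length(rows) != 4) stop("expected 4 count rows for ", name, ", got ", length(rows))
    if (length(unique(lengths(rows))) != 1) stop("ragged count rows for ", name)
    counts <- do.call(rbind, rows)
    # order rows A,C,G,T if the file labels them
    labels <- toupper(substr(block, 1, 1))
    if (all(sort(labels) == c("A", "C", "G", "T"))) counts <- counts[order(match(labels, c("A", "C", "G", "T"))), ]
    pwm_from_counts(counts, pseudocount = pseudocount, background = background, id = name)
  }
  if (length(hdr) == 0) {
    return(parse_block(lines, if (is.null(id)) "motif" else id))
  }
  ends <- c(hdr[-1] - 1, length(lines))
  motifs <- lapply(seq_along(hdr), function(k) {
    name <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "\\s+")[[1]][1]
    list(name = name, block = lines[(hdr[k] + 1):ends[k]])
  })
  pick <- if (is.null(id)) 1 else match(id, vapply(motifs, `[[`, "", "name"))
  if (is.na(pick)) stop("motif ", id, " not found in ", path)
  parse_block(motifs[[pick]]$block, motifs[[pick]]$name)
}

#' Score threshold for a target p-value by exact dynamic programming
#'
#' Computes the exact distribution of the PWM score of a random word drawn
#' from the background model, by column-wise convolution over a discretised
#' score grid, and returns the smallest threshold `t` such that
#' `P(score >= t) <= pvalue`. This reproduces the POSSUM-style per-window
#' p-value cutoff; the default `pvalue = 4^-8` corresponds to the
#' information content of an 8 bp exact word.
#'
#' @param pwm A [pwm_from_counts()] object.
#' @param pvalue Per-window upper-tail probability, in (0, 1].
#' @param bin Score discretisation width in bits (default 0.01).
#' @return Threshold score in bits. If `pvalue` is below the most extreme
#'   achievable tail mass, returns just above the maximum score with a
#'   warning (no window can pass).
#' @export
pwm_score_threshold <- function(pwm, pvalue = 4^-8, bin = 0.01) {
  if (!is.numeric(pvalue) || pvalue <= 0 || pvalue > 1) stop("pvalue must be in (0, 1]")
  lo <- pwm$log_odds
  # -Inf entries (zero probability) can never occur in a passing word drawn
  # from the motif, but a background word can hit them; clamp far below so
  # they fall out of any achievable threshold.
  finite_min <- min(lo[is.finite(lo)])
  clamp <- finite_min * pwm$width - 1000
  lo[!is.finite(lo)] <- clamp
  scaled <- round(lo / bin)
  offset <- -sum(apply(scaled, 2, min))     # shift so grid indices start at 1
  width_span <- sum(apply(scaled, 2, max) - apply(scaled, 2, min))
  dist <- numeric(width_span + 1)           # index = score - min_total + 1
  dist[1] <- 1
  mins <- apply(scaled, 2, min)
  for (j in seq_len(pwm$width)) {
    nxt <- numeric(length(dist))
    for (b in 1:4) {
      shift <- scaled[b, j] - mins[j]
      w <- pwm$background[b]
      if (shift == 0) nxt <- nxt + w * dist
      else nxt[(shift + 1):length(nxt)] <- nxt[(shift + 1):length(nxt)] +
          w * dist[1:(length(nxt) - shift)]
    }
    dist <- nxt
  }
  tail_p <- rev(cumsum(rev(dist)))
  scores <- (seq_along(dist) - 1 - offset) * bin
  # threshold must be an achievable score: the smallest word score whose
  # exact upper tail is within pvalue. Per-column rounding can shift a
  # word's grid score by up to bin/2 each; subtract that slack so exact
  # window scores that map onto the chosen bin still pass.
  ok <- which(tail_p <= pvalue & dist > 0)
  if (length(ok) == 0) {
    warning("pvalue below the smallest achievable tail mass; no window can pass")
    return(max(scores[dist > 0]) + bin)
  }
  scores[min(ok)] - pwm$width * bin / 2
}

# integer codes 1..4 for A,C,G,T; NA for masked (lowercase or N)
encode_free <- function(sequence) {
  match(strsplit(sequence, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
}

scan_one_strand <- function(codes, lo, threshold) {
  w <- ncol(lo)
  L <- length(codes)
  if (L < w) return(integer(0))
  n_win <- L - w + 1
  scores <- numeric(n_win)
  for (j in seq_len(w)) {
    col <- unname(lo[, j])
    scores <- scores + col[codes[j:(j + n_win - 1)]]  # NA propagates masked windows
  }
  hits <- which(!is.na(scores) & scores >= threshold)
  attr(hits, "scores") <- scores[hits]
  hits
}

#' Scan promoters for motif occurrences
#'
#' Slides the PWM over both strands of every promoter. A window is eligible
#' only when all `w` bases lie inside the promoter and are unmasked. The hit
#' anchor is the leftmost promoter-coordinate base of the matched window
#' regardless of strand, reported in TSS-relative coordinates; `distance`
#' is `abs(anchor)`, the quantity entering the position-bias statistic.
#' Overlapping hits are all reported.
#'
#' @param promoters A [promoter_set()].
#' @param pwm A [pwm_from_counts()] object.
#' @param threshold Score cutoff in bits; when `NULL`, derived from `pvalue`
#'   via [pwm_score_threshold()].
#' @param pvalue Per-window p-value used when `threshold` is `NULL`.
#' @return Tibble of hits: `gene`, `anchor` (TSS-relative, signed), `strand`
#'   (`+`/`-`), `score` (bits), `distance` (`abs(anchor)`).
#' @export
scan_promoters <- function(promoters, pwm, threshold = NULL, pvalue = 4^-8) {
  if (is.null(threshold)) threshold <- pwm_score_threshold(pwm, pvalue)
  M <- promoter_upstream(promoters)
  L <- M + promoter_downstream(promoters) + 1L
  if (pwm$width > L) {
    warning("PWM wider than the promoters; no eligible windows")
    return(empty_hits())
  }
  lo_fwd <- pwm$log_odds
  lo_rev <- pwm_revcomp(pwm)$log_odds
  res <- purrr::map2(promoters$gene, promoters$sequence, function(g, s) {
    codes <- encode_free(s)
    fwd <- scan_one_strand(codes, lo_fwd, threshold)
    rev <- scan_one_strand(codes, lo_rev, threshold)
    tibble::tibble(
      gene = g,
      anchor = c(fwd, rev) - 1L - M,
      strand = rep(c("+", "-"), c(length(fwd), length(rev))),
      score = c(attr(fwd, "scores") %||% numeric(0),
                attr(rev, "scores") %||% numeric(0))
    )
  })
  out <- dplyr::arrange(dplyr::bind_rows(res), .data$gene, .data$anchor)
  out$distance <- abs(out$anchor)
  if (nrow(out) == 0) out <- empty_hits()
  out
}

empty_hits <- function() {
  tibble::tibble(gene = character(), anchor = integer(), strand = character(),
                 score = numeric(), distance = integer())
}

#' Write motif hits as TSV
#'
#' @param hits Tibble from [scan_promoters()].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
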