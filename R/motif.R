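#' Extract flank windows around edited sites
#'
#' Builds +/- `halfWidth` windows around each site (length
#' `2 * halfWidth + 1`, clipped and flagged at sequence boundaries) and
#' returns their sequences in transcript orientation: windows on
#' minus-strand genes are reverse-complemented, so downstream motif
#' scanning is single-orientation.
#'
#' @param sites a [SiteExperiment-class] (calibrated, so `tx_strand` is
#'   set) or a `GRanges` of single-base sites with a `tx_strand` column
#' @param genome reference sequences ([Biostrings::DNAStringSet] or FASTA
#'   path)
#' @param halfWidth flank size in bp (default 50)
#' @return a `GRanges` of windows with metadata `anchor` (site position),
#'   `tx_strand`, `clipped`, and `seq` (a `DNAStringSet` in transcript
#'   orientation).
#' @export
extractFlanks <- function(sites, genome, halfWidth = 50) {
  gr <- if (is(sites, "SiteExperiment")) {
    g <- rowRanges(sites)
    g$tx_strand <- rowData(sites)$tx_strand
    g
  } else sites
  if (is.null(gr$tx_strand)) gr$tx_strand <- "+"
  genome <- cleanSeqNames(readGenomeSeq(genome))
  lens <- stats::setNames(Biostrings::width(genome), names(genome))

  anchor <- start(gr)
  chrom <- as.character(seqnames(gr))
  s <- pmax(1L, anchor - halfWidth)
  e <- pmin(lens[chrom], anchor + halfWidth)
  clipped <- s != anchor - halfWidth | e != anchor + halfWidth

  seqs <- Biostrings::DNAStringSet(vapply(seq_along(gr), function(i)
    as.character(Biostrings::subseq(genome[[chrom[i]]], s[i], e[i])),
    character(1)))
  minus <- gr$tx_strand == "-"
  seqs[minus] <- Biostrings::reverseComplement(seqs[minus])

  out <- GRanges(chrom, IRanges(s, e),
                 anchor = anchor, tx_strand = gr$tx_strand,
                 clipped = as.vector(clipped))
  out$seq <- seqs
  names(out) <- names(gr)
  out
}

#' Known-motif enrichment in flank windows
#'
#' Scores each window as a hit when the motif matches anywhere (IUPAC
#' consensus with up to `maxMismatch` mismatches, or a position-weight
#' matrix at `pwmThreshold` of its score range); windows are pre-oriented
#' to transcript strand, so only the given orientation is scanned. The
#' foreground hit count is tested against the background hit fraction by a
#' one-sided binomial test, and Benjamini-Hochberg correction is applied
#' across motifs when several are given. With no background windows, a
#' dinucleotide-shuffled copy of the foreground is used (seed reported).
#'
#' @param windows foreground windows from [extractFlanks()], or a
#'   `DNAStringSet`
#' @param motifs character vector of IUPAC consensus patterns (named to
#'   label results), or a list mixing consensus strings and 4-row
#'   position-weight matrices
#' @param background background windows (same forms), or `NULL` for the
#'   shuffled-foreground fallback
#' @param maxMismatch allowed mismatches for consensus matching
#' @param pwmThreshold score threshold for matrix motifs ("80%" style)
#' @param shuffleSeed seed for the dinucleotide shuffle fallback
#' @return data.frame per motif: foreground/background hit fractions,
#'   binomial `p`, and BH-adjusted `padj`.
#' @export
motifEnrichment <- function(windows, motifs, background = NULL,
                            maxMismatch = 0, pwmThreshold = "80%",
                            shuffleSeed = 0) {
  fg <- windowSeqs(windows)
  if (!length(fg)) stop("no foreground windows")
  if (is.null(background)) {
    message("no background supplied; using dinucleotide-shuffled ",
            "foreground (seed ", shuffleSeed, ")")
    bg <- dinucShuffle(fg, seed = shuffleSeed)
  } else {
    bg <- windowSeqs(background)
    if (!length(bg)) {
      message("empty background; using dinucleotide-shuffled ",
              "foreground (seed ", shuffleSeed, ")")
      bg <- dinucShuffle(fg, seed = shuffleSeed)
    }
  }
  if (is.character(motifs) && is.null(names(motifs)))
    names(motifs) <- motifs
  if (is.list(motifs) && is.null(names(motifs)))
    names(motifs) <- paste0("motif", seq_along(motifs))

  res <- do.call(rbind, lapply(names(motifs), function(id) {
    m <- if (is.list(motifs)) motifs[[id]] else motifs[id]
    fgHits <- motifHits(fg, m, maxMismatch, pwmThreshold)
    bgHits <- motifHits(bg, m, maxMismatch, pwmThreshold)
    fgFrac <- mean(fgHits)
    bgFrac <- mean(bgHits)
    p0 <- min(max(bgFrac, .Machine$double.xmin), 1 - 1e-12)
    p <- stats::pbinom(sum(fgHits) - 1, length(fgHits), p0,
                       lower.tail = FALSE)
    data.frame(motif = id, nForeground = length(fgHits),
               foregroundFraction = fgFrac, backgroundFraction = bgFrac,
               p = p, stringsAsFactors = FALSE)
  }))
  res$padj <- stats::p.adjust(res$p, method = "BH")
  res
}

windowSeqs <- function(x) {
  if (is(x, "DNAStringSet")) return(x)
  if (is(x, "GRanges") && !is.null(x$seq)) return(x$seq)
  if (is.character(x)) return(Biostrings::DNAStringSet(x))
  stop("cannot extract sequences from the supplied windows")
}

#' @rdname motifEnrichment
#' @param seqs a `DNAStringSet`
#' @param motif one consensus string (IUPAC; U is read as T) or a 4-row
#'   position-weight matrix
#' @return `motifHits`: logical vector, one entry per sequence.
#' @export
motifHits <- function(seqs, motif, maxMismatch = 0, pwmThreshold = "80%") {
  if (is.matrix(motif)) {
    rownames(motif) <- rownames(motif) %||% DNA_BASES
    vapply(seq_along(seqs), function(i)
      length(Biostrings::matchPWM(motif, seqs[[i]],
                                  min.score = pwmThreshold)) > 0,
      logical(1))
  } else {
    pat <- gsub("U", "T", toupper(motif))
    Biostrings::vcountPattern(pat, seqs, max.mismatch = maxMismatch,
                              fixed = "subject") > 0
  }
}

#' Dinucleotide-preserving sequence shuffle
#'
#' Shuffles each sequence while preserving its exact dinucleotide
#' composition, by drawing a random Eulerian path through the dinucleotide
#' transition graph (Altschul-Erikson style shuffle); the standard null for
#' motif enrichment in nucleotide sequence.
#'
#' @param seqs a `DNAStringSet` (or character vector)
#' @param seed RNG seed
#' @return a shuffled `DNAStringSet` of the same widths.
#' @export
dinucShuffle <- function(seqs, seed = 0) {
  seqs <- windowSeqs(seqs)
  set.seed(seed)
  out <- vapply(as.character(seqs), shuffleOne, character(1),
                USE.NAMES = FALSE)
  Biostrings::DNAStringSet(out)
}

shuffleOne <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  if (n < 3) return(s)
  succ <- split(ch[-1], factor(ch[-n], levels = unique(ch)))
  term <- ch[n]
  verts <- names(succ)
  # pick, for every non-terminal vertex, a designated last out-edge such
  # that the last edges form a tree into the terminal vertex; then any
  # ordering with those edges last yields a valid Eulerian walk
  repeat {
    last <- vapply(verts, function(v)
      if (v == term || !length(succ[[v]])) NA_character_
      else succ[[v]][sample.int(length(succ[[v]]), 1)], character(1))
    reach <- function(v) {
      seen <- character(0)
      while (!is.na(v) && v != term && !v %in% seen) {
        seen <- c(seen, v)
        v <- if (v %in% names(last)) last[[v]] else NA_character_
      }
      identical(v, term)
    }
    if (all(vapply(setdiff(verts, term), reach, logical(1)))) break
  }
  bag <- lapply(verts, function(v) {
    e <- succ[[v]]
    if (v %in% names(last) && !is.na(last[[v]])) {
      e <- e[-match(last[[v]], e)]
      c(sample(e), last[[v]])
    } else sample(e)
  })
  names(bag) <- verts
  used <- stats::setNames(integer(length(verts)), verts)
  res <- character(n)
  res[1] <- ch[1]
  for (i in 2:n) {
    v <- res[i - 1]
    used[v] <- used[v] + 1L
    res[i] <- bag[[v]][used[v]]
  }
  paste(res, collapse = "")
}
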