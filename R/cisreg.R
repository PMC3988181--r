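#' Extract promoter sequences from a genome and gene models
#'
#' The promoter of a gene is the stretch of up to \code{length} bases
#' immediately upstream of its translation start (the CDS start), read
#' 5'->3' toward the gene. On the plus strand this is the genomic window
#' [CDS start - length, CDS start - 1]; on the minus strand it is the
#' reverse complement of the window just 3' of the CDS end in genome
#' coordinates. Windows are truncated (with a warning) at contig
#' boundaries; genes lacking a CDS record are skipped, not fatal.
#'
#' @param genome \code{DNAStringSet} or path to a FASTA file.
#' @param models \code{GRanges} with \code{type} and \code{ID} metadata
#'   columns (CDS records used), or path to a GFF3 file.
#' @param genes Gene ids to extract; default: all genes with a CDS.
#' @param length Promoter length in bases (default 2000).
#' @return Named character vector of promoter sequences (class
#'   \code{promoter_set}); attribute \code{skipped} lists genes without a
#'   CDS record.
#' @export
extract_promoters <- function(genome, models, genes = NULL, length = 2000) {
  if (is.character(genome) && length(genome) == 1)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*", "", names(genome))
  if (is.character(models) && length(models) == 1)
    models <- rtracklayer::import(models, format = "gff3")
  cds <- models[models$type == "CDS"]
  cds_gene <- as.character(cds$ID)
  if (is.null(genes)) genes <- unique(cds_gene)

  skipped <- setdiff(genes, cds_gene)
  if (length(skipped))
    warning(length(skipped), " gene(s) without CDS record skipped")
  genes <- setdiff(genes, skipped)

  seqs <- stats::setNames(character(length(genes)), genes)
  truncated <- character(0)
  for (g in genes) {
    rec <- cds[cds_gene == g]
    contig <- as.character(GenomicRanges::seqnames(rec))[1]
    clen <- Biostrings::width(genome[contig])
    strand <- as.character(GenomicRanges::strand(rec))[1]
    if (strand == "-") {
      e <- max(GenomicRanges::end(rec))
      from <- e + 1L
      to <- min(e + length, clen)
      if (from > to) { seqs[g] <- ""; truncated <- c(truncated, g); next }
      s <- Biostrings::subseq(genome[[contig]], from, to)
      seqs[g] <- as.character(Biostrings::reverseComplement(s))
      if (to - from + 1L < length) truncated <- c(truncated, g)
    } else {
      st <- min(GenomicRanges::start(rec))
      from <- max(1L, st - length)
      to <- st - 1L
      if (from > to) { seqs[g] <- ""; truncated <- c(truncated, g); next }
      seqs[g] <- as.character(Biostrings::subseq(genome[[contig]], from, to))
      if (to - from + 1L < length) truncated <- c(truncated, g)
    }
  }
  if (length(truncated))
    warning(length(truncated),
            " promoter(s) truncated at contig boundaries")
  structure(seqs, skipped = skipped, class = "promoter_set")
}

# --- k-mer window encoding -------------------------------------------

# Encode all k-length windows of a set of sequences as base-4 integers
# (A=0, C=1, G=2, T=3); windows containing any other character are NA.
# Returns list(codes = integer vector, seq_of = index of source sequence).
encode_windows <- function(seqs, k) {
  if (!length(seqs)) stop("no sequences to encode")
  sep <- strrep("N", k)
  joined <- paste(seqs, collapse = sep)
  b <- match(strsplit(joined, "")[[1]], c("A", "C", "G", "T")) - 1L
  L <- length(b)
  if (L < k) return(list(codes = integer(0), seq_of = integer(0)))
  nw <- L - k + 1L
  codes <- numeric(nw)
  for (j in 0:(k - 1)) codes <- codes + b[(1 + j):(nw + j)] * 4^(k - 1 - j)
  lens <- nchar(seqs)
  starts <- cumsum(c(1, utils::head(lens + k, -1)))
  seq_of <- rep(NA_integer_, nw)
  for (i in seq_along(seqs)) {
    n_i <- lens[i] - k + 1L
    if (n_i > 0)
      seq_of[starts[i]:(starts[i] + n_i - 1L)] <- i
  }
  ok <- !is.na(seq_of) & !is.na(codes)   # windows with N never match
  list(codes = as.integer(codes[ok]), seq_of = seq_of[ok])
}

kmer_to_code <- function(kmer) {
  b <- match(strsplit(kmer, "")[[1]], c("A", "C", "G", "T")) - 1L
  if (anyNA(b)) stop("motif must be over A,C,G,T: ", kmer)
  sum(b * 4^(rev(seq_along(b)) - 1))
}

code_to_kmer <- function(code, k) {
  bases <- c("A", "C", "G", "T")
  out <- character(k)
  for (j in k:1) {
    out[j] <- bases[code %% 4 + 1]
    code <- code %/% 4
  }
  paste(out, collapse = "")
}

# digit of code at position p (1 = leftmost of k)
code_digit <- function(code, p, k) (code %/% 4^(k - p)) %% 4

# Exact k-mer counts over all 4^k codes from encoded windows.
exact_kmer_counts <- function(enc, k) {
  tabulate(enc$codes + 1L, nbins = 4^k)
}

# Mismatch-tolerant counts for every motif: counts[m] = number of windows
# whose k-mer lies within Hamming distance max_mm of m. Computed by
# position-marginal sums over the exact count vector (no per-motif
# neighborhood enumeration).
mismatch_tolerant_counts <- function(counts, k, max_mm) {
  if (max_mm == 0) return(counts)
  m <- seq_along(counts) - 1L
  S1 <- numeric(length(counts))
  rest_idx <- function(positions) {
    # index of the k-mer with the given digit positions removed
    r <- numeric(length(m))
    shift <- 0
    keep <- setdiff(seq_len(k), positions)
    for (j in rev(keep)) {
      r <- r + code_digit(m, j, k) * 4^shift
      shift <- shift + 1
    }
    r
  }
  for (p in seq_len(k)) {
    r <- rest_idx(p)
    Tp <- as.numeric(rowsum(counts, r))        # ordered by rest code
    S1 <- S1 + Tp[r + 1]
  }
  n1 <- S1 - k * counts
  if (max_mm == 1) return(counts + n1)
  if (max_mm != 2) stop("max_mm must be 0, 1 or 2")
  S2 <- numeric(length(counts))
  pairs <- utils::combn(k, 2)
  for (j in seq_len(ncol(pairs))) {
    r <- rest_idx(pairs[, j])
    Tpq <- as.numeric(rowsum(counts, r))
    S2 <- S2 + Tpq[r + 1]
  }
  n2 <- S2 - choose(k, 2) * counts - (k - 1) * n1
  counts + n1 + n2
}

#' Count mismatch-tolerant occurrences of a k-mer in promoters
#'
#' Sliding-window count of windows within Hamming distance \code{max_mm}
#' of the motif; overlapping occurrences all count, and windows containing
#' a non-ACGT character never match.
#'
#' @param promoters Named character vector of sequences (a
#'   \code{promoter_set}).
#' @param motif A 6- or 8-mer over ACGT.
#' @param max_mm Allowed mismatches (0-2).
#' @param both_strands Also accept windows matching the reverse complement
#'   of the motif (each window counted once).
#' @return Integer vector \code{c(occurrences, seqs_with_hit)}.
#' @export
count_kmer <- function(promoters, motif, max_mm = 0, both_strands = FALSE) {
  k <- nchar(motif)
  if (!k %in% c(6L, 8L)) stop("motif length must be 6 or 8")
  target <- kmer_to_code(motif)
  enc <- encode_windows(as.character(promoters), k)
  if (!length(enc$codes)) return(c(occurrences = 0L, seqs_with_hit = 0L))
  dist <- numeric(length(enc$codes))
  for (p in seq_len(k))
    dist <- dist + (code_digit(enc$codes, p, k) !=
                      code_digit(target, p, k))
  hit <- dist <= max_mm
  if (both_strands) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    target_rc <- kmer_to_code(rc)
    dist_rc <- numeric(length(enc$codes))
    for (p in seq_len(k))
      dist_rc <- dist_rc + (code_digit(enc$codes, p, k) !=
                              code_digit(target_rc, p, k))
    hit <- hit | dist_rc <= max_mm
  }
  c(occurrences = sum(hit),
    seqs_with_hit = length(unique(enc$seq_of[hit])))
}

# default mismatch allowance by motif length (1 for 6-mers, 2 for 8-mers)
default_mismatch <- function(k) if (k == 6) 1L else 2L

#' Exhaustive k-mer overrepresentation analysis
#'
#' Scores every one of the 4^k candidate motifs by its mismatch-tolerant
#' occurrence count in the foreground promoters against the rate observed
#' in the background promoters. Significance is the upper-tail binomial
#' probability of at least the observed foreground count given the
#' background per-window rate, Bonferroni-adjusted over the 4^k candidates
#' (set \code{correct = "none"} for raw p filtering). Significant motifs
#' are ranked by log2 odds of foreground over background rate and
#' truncated to \code{top}.
#'
#' @param fg,bg Foreground / background promoter sets (disjoint genes).
#' @param k Motif length, 6 or 8.
#' @param alpha Significance level on the (adjusted) enrichment p.
#' @param top Maximum number of motifs reported.
#' @param max_mm Mismatch allowance (default 1 for k=6, 2 for k=8).
#' @param correct Multiple-testing handling of the 4^k candidate tests.
#' @return Object of class \code{motif_report}: data frame with columns
#'   motif, fg_count, fg_seqs_with_hit, fg_windows, bg_count, bg_rate,
#'   log_odds, p_enrich (raw binomial tail), p_adj, and a \code{matches}
#'   list-column (filled by \code{\link{match_catalog}}).
#' @export
discover_motifs <- function(fg, bg, k = 6, alpha = 0.05, top = 10,
                            max_mm = default_mismatch(k),
                            correct = c("bonferroni", "none")) {
  correct <- match.arg(correct)
  if (!length(fg)) stop("foreground promoter set is empty")
  if (!length(bg)) stop("background promoter set is empty")
  if (!k %in% c(6L, 8L)) stop("k must be 6 or 8")
  if (length(intersect(names(fg), names(bg))))
    stop("foreground and background gene sets must be disjoint")

  enc_fg <- encode_windows(as.character(fg), k)
  enc_bg <- encode_windows(as.character(bg), k)
  fg_windows <- length(enc_fg$codes)
  bg_windows <- length(enc_bg$codes)
  if (!fg_windows || !bg_windows)
    stop("no valid windows in foreground or background")

  fgc <- mismatch_tolerant_counts(exact_kmer_counts(enc_fg, k), k, max_mm)
  bgc <- mismatch_tolerant_counts(exact_kmer_counts(enc_bg, k), k, max_mm)
  bg_rate <- bgc / bg_windows
  p <- stats::pbinom(fgc - 1, fg_windows, bg_rate, lower.tail = FALSE)
  p_adj <- if (correct == "bonferroni") pmin(p * 4^k, 1) else p

  pseudo <- 0.5 / bg_windows
  log_odds <- log2((fgc / fg_windows) / pmax(bg_rate, pseudo))

  keep <- which(p_adj < alpha & fgc > 0)
  keep <- keep[order(-log_odds[keep], p[keep], keep)]
  keep <- utils::head(keep, top)

  if (!length(keep)) {
    res <- data.frame(motif = character(0), fg_count = integer(0),
                      fg_seqs_with_hit = integer(0),
                      fg_windows = integer(0), bg_count = integer(0),
                      bg_rate = numeric(0), log_odds = numeric(0),
                      p_enrich = numeric(0), p_adj = numeric(0),
                      stringsAsFactors = FALSE)
    res$matches <- list()
    return(structure(res, k = k, max_mm = max_mm,
                     class = c("motif_report", "data.frame")))
  }
  motifs <- vapply(keep - 1L, code_to_kmer, character(1), k = k)
  seq_hits <- vapply(motifs, function(mm) {
    count_kmer(fg, mm, max_mm)[["seqs_with_hit"]]
  }, numeric(1))

  res <- data.frame(motif = motifs,
                    fg_count = fgc[keep],
                    fg_seqs_with_hit = as.integer(seq_hits),
                    fg_windows = fg_windows,
                    bg_count = bgc[keep],
                    bg_rate = bg_rate[keep],
                    log_odds = log_odds[keep],
                    p_enrich = p[keep],
                    p_adj = p_adj[keep],
                    stringsAsFactors = FALSE)
  res$matches <- replicate(nrow(res), NULL, simplify = FALSE)
  rownames(res) <- NULL
  structure(res, k = k, max_mm = max_mm,
            class = c("motif_report", "data.frame"))
}

# expand an IUPAC consensus into a list of allowed-base sets
iupac_classes <- function(consensus, accession = "?") {
  codes <- strsplit(toupper(consensus), "")[[1]]
  map <- Biostrings::IUPAC_CODE_MAP
  bad <- setdiff(codes, names(map))
  if (length(bad))
    stop(sprintf("invalid IUPAC code '%s' in catalog entry %s",
                 bad[1], accession))
  lapply(codes, function(cc) strsplit(map[[cc]], "")[[1]])
}

# minimum mismatches over ungapped full-containment alignments of a motif
# against an IUPAC consensus (overhanging positions are not compared)
iupac_min_mismatch <- function(motif, classes) {
  mb <- strsplit(motif, "")[[1]]
  k <- length(mb)
  lc <- length(classes)
  best <- Inf
  if (lc >= k) {
    for (off in 0:(lc - k)) {
      mm <- sum(vapply(seq_len(k), function(i)
        !(mb[i] %in% classes[[off + i]]), logical(1)))
      best <- min(best, mm)
    }
  } else {
    for (off in 0:(k - lc)) {
      mm <- sum(vapply(seq_len(lc), function(i)
        !(mb[off + i] %in% classes[[i]]), logical(1)))
      best <- min(best, mm)
    }
  }
  best
}

#' Match discovered motifs against a known-CRE catalog
#'
#' Compares each motif with each catalog consensus by ungapped alignment
#' (the shorter fully inside the longer), counting positions whose base
#' falls outside the consensus' IUPAC class. A catalog entry matches at
#' <= 1 mismatch for 6-mers and <= 2 for 8-mers. Reverse-complement
#' matching is on by default since cis-elements are double-stranded.
#'
#' @param report A \code{motif_report}.
#' @param catalog Data frame with columns \code{accession},
#'   \code{consensus} (IUPAC), \code{description}.
#' @param rc Also try the reverse complement of each motif.
#' @return The report with its \code{matches} list-column filled: each
#'   entry a data frame (accession, mismatches, description) sorted by
#'   mismatch count.
#' @export
match_catalog <- function(report, catalog, rc = TRUE) {
  if (!nrow(catalog)) stop("catalog is empty")
  classes <- lapply(seq_len(nrow(catalog)), function(i)
    iupac_classes(catalog$consensus[i], catalog$accession[i]))
  for (i in seq_len(nrow(report))) {
    motif <- report$motif[i]
    k <- nchar(motif)
    allowed <- default_mismatch(k)
    variants <- motif
    if (rc)
      variants <- c(variants, as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(motif))))
    mm <- vapply(classes, function(cl)
      min(vapply(variants, iupac_min_mismatch, numeric(1), classes = cl)),
      numeric(1))
    hit <- which(mm <= allowed)
    hit <- hit[order(mm[hit], catalog$accession[hit])]
    report$matches[[i]] <- if (length(hit))
      data.frame(accession = catalog$accession[hit],
                 mismatches = as.integer(mm[hit]),
                 description = catalog$description[hit],
                 stringsAsFactors = FALSE)
    else
      data.frame(accession = character(0), mismatches = integer(0),
                 description = character(0))
  }
  report
}

#' @export
print.motif_report <- function(x, ...) {
  cat(sprintf("Motif report: %d overrepresented %d-mers\n", nrow(x),
              attr(x, "k") %||% nchar(x$motif[1])))
  flat <- as.data.frame(x)[, setdiff(names(x), "matches"), drop = FALSE]
  if (!is.null(x$matches) && nrow(x))
    flat$best_match <- vapply(x$matches, function(mt)
      if (is.null(mt) || !nrow(mt)) "" else mt$accession[1], character(1))
  print(flat)
  invisible(x)
}

#' Read a cis-regulatory element catalog TSV
#'
#' Columns: accession, consensus (IUPAC), description.
#'
#' @param path TSV path.
#' @return The catalog data frame.
#' @export
read_cre_catalog <- function(path) {
  cat <- read_tsv(path)
  need <- c("accession", "consensus", "description")
  if (!all(need %in% names(cat)))
    stop("catalog needs columns: ", paste(need, collapse = ", "))
  cat
}

#' Write a motif report as TSV
#'
#' One row per (motif, catalog match) with columns module, rank, motif,
#' p_enrich, fg_count, log_odds, accession, mismatches, description;
#' motifs without a match get empty accession fields.
#'
#' @param report A \code{motif_report} (or list of them, named by module).
#' @param path Output path.
#' @param module Module label for the report (ignored for named lists).
#' @export
write_motif_report <- function(report, path, module = NA) {
  reports <- if (inherits(report, "motif_report"))
    stats::setNames(list(report), module) else report
  rows <- list()
  for (mod in names(reports)) {
    rep_i <- reports[[mod]]
    for (i in seq_len(nrow(rep_i))) {
      mt <- rep_i$matches[[i]]
      if (is.null(mt) || !nrow(mt))
        mt <- data.frame(accession = "", mismatches = NA,
                         description = "")
      rows[[length(rows) + 1L]] <- data.frame(
        module = mod, rank = i, motif = rep_i$motif[i],
        p_enrich = signif(rep_i$p_enrich[i], 3),
        fg_count = rep_i$fg_count[i],
        log_odds = round(rep_i$log_odds[i], 3),
        accession = mt$accession, mismatches = mt$mismatches,
        description = mt$description, stringsAsFactors = FALSE)
    }
  }
  write_tsv(do.call(rbind, rows) %||%
              data.frame(module = character(0)), path)
}
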