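# Sequence-level statistics: per-gene uracil density (T fraction of the
# coding sequence; U in the mRNA), relative codon usage of hydrophobic
# amino acids with the most U-rich codon(s) flagged, and the
# membrane-vs-cytoplasmic comparison of uracil densities.

HYDROPHOBIC_AA <- c("A", "V", "L", "I", "F", "M", "W")

.as_sequences <- function(x) {
  if (inherits(x, "DNAStringSet")) {
    s <- as.character(x)
  } else if (inherits(x, "DNAString")) {
    s <- as.character(x)
    names(s) <- "seq"
  } else if (is.character(x)) {
    s <- toupper(x)
  } else {
    stop("sequences must be character, DNAString or DNAStringSet")
  }
  if (any(!nzchar(s))) stop("empty sequence")
  s
}

#' Uracil density of coding sequences
#'
#' The number of thymines divided by sequence length (T in DNA codes for
#' U in the mRNA).  Only canonical bases are accepted; ambiguity codes
#' raise an error listing the offending positions.
#'
#' @param seqs character vector, `DNAString` or `DNAStringSet` of coding
#'   sequences (A/C/G/T only).
#' @return numeric vector of fractions in `[0, 1]` (named if the input
#'   is named).
#' @export
uracil_density <- function(seqs) {
  s <- .as_sequences(seqs)
  bad <- gregexpr("[^ACGT]", s)
  for (i in seq_along(s)) {
    pos <- bad[[i]]
    if (pos[1] != -1L) {
      stop(sprintf(
        "non-canonical base(s) in sequence %s at position(s) %s",
        names(s)[i] %||% i, paste(pos, collapse = ", ")
      ))
    }
  }
  counts <- vapply(strsplit(s, ""), function(ch) sum(ch == "T"), numeric(1))
  setNames(counts / nchar(s), names(s))
}

.codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Relative codon usage of hydrophobic amino acids
#'
#' Codon counts are pooled over all records; per synonymous family the
#' usage fractions sum to 1 and the codon(s) of maximal uracil (T)
#' content are flagged (ties all flagged).  Internal stop codons are
#' counted, reported in the `"internal_stops"` attribute and excluded
#' from the totals; a terminal stop codon is ignored.
#'
#' @param seqs coding sequences (lengths divisible by 3).
#' @param amino_acids amino-acid set (one-letter codes); defaults to the
#'   hydrophobic set A, V, L, I, F, M, W.
#' @param genetic_code named codon -> amino-acid map (default
#'   [Biostrings::GENETIC_CODE]).
#' @return data.frame of class `codon_bias_table` with columns `aa`,
#'   `codon`, `count`, `fraction`, `u_count`, `max_u`.
#' @export
codon_bias <- function(seqs, amino_acids = HYDROPHOBIC_AA,
                       genetic_code = Biostrings::GENETIC_CODE) {
  s <- .as_sequences(seqs)
  codons <- unlist(lapply(s, function(x) {
    cs <- .codon_split(x)
    if (length(cs) && genetic_code[[cs[length(cs)]]] == "*") {
      cs <- cs[-length(cs)] # terminal stop
    }
    cs
  }), use.names = FALSE)
  aa_of <- unname(genetic_code[codons])
  internal_stops <- sum(aa_of == "*")
  codons <- codons[aa_of != "*"]
  aa_of <- aa_of[aa_of != "*"]
  rows <- do.call(rbind, lapply(amino_acids, function(aa) {
    fam <- sort(names(genetic_code)[genetic_code == aa])
    cnt <- vapply(fam, function(cd) sum(codons == cd), numeric(1))
    tot <- sum(cnt)
    u <- vapply(strsplit(fam, ""), function(ch) sum(ch == "T"), numeric(1))
    data.frame(
      aa = aa, codon = fam, count = cnt,
      fraction = if (tot > 0) cnt / tot else rep(NA_real_, length(fam)),
      u_count = u,
      max_u = u == max(u),
      stringsAsFactors = FALSE
    )
  }))
  rownames(rows) <- NULL
  attr(rows, "internal_stops") <- internal_stops
  class(rows) <- c("codon_bias_table", "data.frame")
  rows
}

#' Compare uracil densities between gene classes
#'
#' Welch two-sample t-test of per-gene uracil densities between the
#' membrane and cytoplasmic classes, with per-class summaries.
#'
#' @param densities data.frame with columns `density` and `class`
#'   (two classes, each with >= 2 records).
#' @return list of class `class_comparison`: `summary` (per class n,
#'   median, q1, q3, mean, sd), `statistic`, `df`, `p_value`, `method`.
#' @export
compare_classes <- function(densities) {
  stopifnot(all(c("density", "class") %in% names(densities)))
  cls <- unique(densities$class)
  if (length(cls) != 2) stop("exactly two gene classes are required")
  groups <- split(densities$density, densities$class)
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each class needs at least 2 records")
  }
  if (all(vapply(groups, var, numeric(1)) == 0)) {
    stop("degenerate data: zero variance in both classes")
  }
  tt <- t.test(groups[[1]], groups[[2]], var.equal = FALSE)
  summ <- do.call(rbind, lapply(names(groups), function(g) {
    x <- groups[[g]]
    data.frame(class = g, n = length(x), median = median(x),
               q1 = unname(quantile(x, 0.25)), q3 = unname(quantile(x, 0.75)),
               mean = mean(x), sd = sd(x), stringsAsFactors = FALSE)
  }))
  structure(
    list(summary = summ, statistic = unname(tt$statistic),
         df = unname(tt$parameter), p_value = tt$p.value,
         method = "Welch two-sample t-test"),
    class = "class_comparison"
  )
}

#' @export
print.class_comparison <- function(x, ...) {
  cat(sprintf("%s: t = %.3f, df = %.1f, p = %.3g\n",
              x$method, x$statistic, x$df, x$p_value))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Read coding sequences with gene classes
#'
#' @param fasta path to a FASTA file of coding sequences.
#' @param classes_csv path to a CSV with columns `gene_id`, `class`
#'   (membrane / cytoplasmic); genes absent from the table are marked
#'   `unassigned`.
#' @return data.frame with `gene_id`, `sequence`, `class`.
#' @export
read_sequence_records <- function(fasta, classes_csv = NULL) {
  set <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(set))
  out <- data.frame(gene_id = ids, sequence = as.character(set),
                    class = "unassigned", stringsAsFactors = FALSE)
  if (!is.null(classes_csv)) {
    cls <- read.csv(classes_csv, stringsAsFactors = FALSE)
    m <- match(out$gene_id, cls$gene_id)
    out$class[!is.na(m)] <- cls$class[m[!is.na(m)]]
  }
  rownames(out) <- NULL
  out
}

#' Synthesize coding sequences with a controlled uracil density
#'
#' Draws codons i.i.d. with per-base T probability tuned to the requested
#' density (demo/testing helper; real analyses consume annotated CDSs).
#' Stop codons are excluded so the uracil density is the only controlled
#' property.
#'
#' @param n number of genes.
#' @param n_codons codons per gene.
#' @param target_density approximate per-gene T fraction.
#' @param seed integer seed.
#' @return character vector of sequences.
#' @export
synth_coding_sequences <- function(n, n_codons = 300, target_density = 0.3,
                                   seed = 1L) {
  stopifnot(target_density > 0, target_density < 1)
  with_seed(seed, {
    other <- (1 - target_density) / 3
    probs <- c(A = other, C = other, G = other, T = target_density)
    stops <- c("TAA", "TAG", "TGA")
    vapply(seq_len(n), function(i) {
      codons <- character(n_codons)
      for (j in seq_len(n_codons)) {
        repeat {
          cd <- paste(sample(names(probs), 3, replace = TRUE, prob = probs),
                      collapse = "")
          if (!cd %in% stops) break
        }
        codons[j] <- cd
      }
      paste(codons, collapse = "")
    }, character(1))
  })
}
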