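# Degenerate-codon math for site-saturation mutagenesis libraries.
# Translation uses the standard genetic code (the E. coli host uses table 1).

IUPAC_DNA <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

#' Amino-acid profile of a degenerate codon scheme
#'
#' Exhaustively expands a three-letter IUPAC degenerate codon (e.g. `"NNK"`:
#' N = A/C/G/T, K = G/T, 32 codons) and translates every concrete codon with
#' the standard genetic code, tallying codon counts and per-draw
#' probabilities for each amino acid and for stop codons.
#'
#' @param scheme Three IUPAC nucleotide symbols, e.g. `"NNK"`, `"NNS"`,
#'   `"NNN"`, or a concrete codon like `"GCT"`.
#' @return Object of class `aa_profile`: `scheme`, `n_codons`, `codons`
#'   (character vector of the expansion), and `profile`, a data frame with
#'   columns `residue` (one-letter amino acid, `"*"` for stop), `codons`
#'   (count) and `prob` (codons / n_codons; probabilities sum to 1).
#' @export
degenerate_codon_profile <- function(scheme = "NNK") {
  if (!is.character(scheme) || length(scheme) != 1L || nchar(scheme) != 3L)
    stop_input("'scheme' must be a single 3-letter codon string")
  sym <- strsplit(toupper(scheme), "")[[1]]
  bad <- setdiff(sym, names(IUPAC_DNA))
  if (length(bad))
    stop_input("invalid IUPAC symbol '%s' in scheme '%s'", bad[1], scheme)
  codons <- as.vector(outer(outer(IUPAC_DNA[[sym[1]]], IUPAC_DNA[[sym[2]]], paste0),
                            IUPAC_DNA[[sym[3]]], paste0))
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  tab <- table(factor(aa, levels = sort(unique(aa))))
  profile <- data.frame(residue = names(tab), codons = as.integer(tab),
                        prob = as.integer(tab) / length(codons),
                        row.names = NULL)
  structure(list(scheme = toupper(scheme), n_codons = length(codons),
                 codons = codons, profile = profile),
            class = "aa_profile")
}

#' @export
print.aa_profile <- function(x, ...) {
  nstop <- sum(x$profile$codons[x$profile$residue == "*"])
  cat(sprintf("%s: %d codons -> %d amino acids, %d stop codon(s)\n",
              x$scheme, x$n_codons,
              sum(x$profile$residue != "*"), nstop))
  invisible(x)
}

#' Screening coverage of a site-saturation library
#'
#' For `n_clones` independent, codon-unbiased clones drawn from a
#' degenerate-codon profile: the expected fraction of amino acids observed
#' (mean over amino acids of `1 - (1 - p_aa)^n`), the probability that all
#' amino acids are observed (inclusion-exclusion over amino acids, grouped
#' by distinct codon multiplicity), and the smallest library size at which
#' the rarest amino acid is seen with the target confidence. Stop codons
#' are not coverage targets (a stop at the randomized position is a
#' non-variant) but remain part of the per-draw probability space.
#'
#' @param profile An [degenerate_codon_profile()] result.
#' @param n_clones Number of clones screened (>= 0).
#' @param target Confidence for `clones_for_target`, in (0, 1)
#'   (default 0.95).
#' @return Object of class `coverage_estimate`: `n_clones`,
#'   `expected_fraction_covered`, `p_all_covered`, `clones_for_target`.
#' @export
library_coverage <- function(profile, n_clones, target = 0.95) {
  stopifnot(inherits(profile, "aa_profile"))
  check_number(n_clones, "n_clones", min = 0)
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1)
    stop_input("'target' must be in (0, 1)")
  p <- profile$profile
  aa <- p[p$residue != "*", , drop = FALSE]
  probs <- aa$prob
  n <- n_clones

  expected <- mean(1 - (1 - probs)^n)
  p_all <- p_all_covered(probs, n)
  p_min <- min(probs)
  n_target <- ceiling(log(1 - target) / log(1 - p_min))
  # guard against floating-point edge at the boundary
  while (1 - (1 - p_min)^n_target < target) n_target <- n_target + 1L
  while (n_target > 1 && 1 - (1 - p_min)^(n_target - 1) >= target)
    n_target <- n_target - 1L
  structure(
    list(n_clones = n_clones, expected_fraction_covered = expected,
         p_all_covered = p_all, clones_for_target = as.integer(n_target),
         target = target),
    class = "coverage_estimate")
}

# P(every amino acid with per-draw probability probs[i] is seen at least
# once in n draws), by inclusion-exclusion. Amino acids are grouped by
# identical probability so the sum runs over counts per group rather than
# all 2^k subsets: sum over (j_1..j_G) of prod C(m_g, j_g) * (-1)^sum(j) *
# (1 - sum(j_g * q_g))^n.
p_all_covered <- function(probs, n) {
  if (n <= 0) return(0)
  grp <- table(probs)
  q <- as.numeric(names(grp))   # distinct probabilities
  m <- as.integer(grp)          # multiplicities
  idx <- expand.grid(lapply(m, function(mm) 0:mm))
  total <- 0
  for (r in seq_len(nrow(idx))) {
    j <- as.integer(idx[r, ])
    sign <- (-1)^sum(j)
    weight <- prod(choose(m, j))
    miss <- 1 - sum(j * q)
    total <- total + sign * weight * max(miss, 0)^n
  }
  min(max(total, 0), 1)
}

#' @export
print.coverage_estimate <- function(x, ...) {
  cat(sprintf("Coverage at n = %d clones: E[fraction seen] = %.4f, P(all seen) = %.4f\n",
              x$n_clones, x$expected_fraction_covered, x$p_all_covered))
  cat(sprintf("Clones for %.0f%% confidence on the rarest amino acid: %d\n",
              100 * x$target, x$clones_for_target))
  invisible(x)
}
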