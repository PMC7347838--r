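# Table-shaped synthetic inputs: RADseq-like marker maps and per-gene
# P-value matrices from four branch-site selection tests.

chrom_lengths_of <- function(x) {
  if (inherits(x, "agp")) return(agp_object_lengths(x))
  if (is.character(x)) return(seq_lengths(x))
  stopifnot(is.numeric(x), !is.null(names(x)))
  x
}

#' Simulate a linkage-map marker placement table
#'
#' Places markers uniformly on the assembly's chromosomes. Each chromosome
#' corresponds to one linkage group; a concordant marker's genetic position
#' grows monotonically with its physical position, so within-group genetic
#' order follows physical order. Exactly
#' `round(n_markers * discordant_fraction)` markers are reassigned to a
#' *different* linkage group (with an arbitrary genetic position there),
#' emulating mapping discordance.
#'
#' @param assembly Chromosome sequences (named character vector), named
#'   length vector, or an `agp` assembly. Needs >= 2 chromosomes when
#'   `discordant_fraction > 0`.
#' @param n_markers Number of markers (>= 1).
#' @param discordant_fraction Fraction of discordant markers in `[0, 1]`.
#' @param seed Integer seed.
#' @return data.frame: `marker_id`, `linkage_group`, `cM`, `chrom`, `pos`
#'   (0-based bp), `mapq`, and truth column `discordant`.
#' @export
simulate_marker_map <- function(assembly, n_markers, discordant_fraction = 0,
                                seed = 1) {
  fail_if(n_markers < 1, "n_markers must be >= 1")
  stopifnot(discordant_fraction >= 0, discordant_fraction <= 1)
  lens <- chrom_lengths_of(assembly)
  groups <- stats::setNames(sprintf("LG%02d", seq_along(lens)), names(lens))
  n_disc <- round(n_markers * discordant_fraction)
  fail_if(n_disc > 0 && length(lens) < 2,
          "discordant markers require >= 2 chromosomes")
  with_seed(seed, {
    chrom <- sample(names(lens), n_markers, replace = TRUE,
                    prob = lens / sum(lens))
    pos <- floor(stats::runif(n_markers) * lens[chrom])
    cm <- round(100 * pos / lens[chrom], 3)
    lg <- unname(groups[chrom])
    discordant <- rep(FALSE, n_markers)
    if (n_disc > 0) {
      idx <- sample.int(n_markers, n_disc)
      discordant[idx] <- TRUE
      for (i in idx) {
        other <- setdiff(unname(groups), groups[chrom[i]])
        lg[i] <- if (length(other) == 1) other else sample(other, 1)
        cm[i] <- round(stats::runif(1, 0, 100), 3)
      }
    }
    data.frame(marker_id = sprintf("mk%05d", seq_len(n_markers)),
               linkage_group = lg, cM = cm, chrom = unname(chrom),
               pos = unname(pos), mapq = 60, discordant = discordant,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a per-gene four-test P-value matrix
#'
#' Emulates the input of consensus positive-selection calling: for each
#' gene, four P-values (two codon-alignment methods, each tested with and
#' without alignment gaps). Null genes draw four i.i.d. Uniform(0,1)
#' values; selected genes draw four i.i.d. Beta(`alt_strength`, 1) values,
#' a single-parameter alternative whose CDF `x^alt_strength` gives
#' closed-form power calculations.
#'
#' @param n_genes Number of genes.
#' @param frac_selected Fraction of genes under selection, in `[0, 1]`.
#' @param alt_strength Beta shape in `(0, 1]`; smaller means stronger
#'   selection signal (P-values shrink toward 0).
#' @param seed Integer seed.
#' @return data.frame: `gene`, `pA_gap`, `pA_nogap`, `pB_gap`, `pB_nogap`,
#'   and truth column `selected`.
#' @export
simulate_psg_table <- function(n_genes, frac_selected = 0, alt_strength = 0.05,
                               seed = 1) {
  stopifnot(n_genes >= 1, frac_selected >= 0, frac_selected <= 1,
            alt_strength > 0, alt_strength <= 1)
  n_sel <- round(n_genes * frac_selected)
  with_seed(seed, {
    selected <- rep(FALSE, n_genes)
    if (n_sel > 0) selected[sample.int(n_genes, n_sel)] <- TRUE
    draw <- function() {
      p <- stats::runif(n_genes)
      p[selected] <- stats::rbeta(sum(selected), alt_strength, 1)
      p
    }
    data.frame(gene = sprintf("g%05d", seq_len(n_genes)),
               pA_gap = draw(), pA_nogap = draw(),
               pB_gap = draw(), pB_nogap = draw(),
               selected = selected, stringsAsFactors = FALSE)
  })
}
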