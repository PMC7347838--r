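# Consensus positive-selection calling over four branch-site tests,
# ohnolog paralog collapsing, and hypergeometric gene-set enrichment.

psg_test_cols <- c("pA_gap", "pA_nogap", "pB_gap", "pB_nogap")

#' Consensus-calling policy
#'
#' The default mirrors the conservative voting rule: a gene is called
#' positively selected when an uncorrected P < 0.05 is reached in at
#' least three of the four tests, and the largest P-value among the
#' passing tests is assigned to the gene.
#'
#' @param alpha Per-test significance level.
#' @param min_passing How many of the four tests must pass (1-4).
#' @param assign_rule `"max-passing"` (default; maximum over all passing
#'   tests, the conservative reading when all four pass) or `"max-top3"`
#'   (maximum over the three smallest passing P-values).
#' @return List of class `consensus_policy`.
#' @export
consensus_policy <- function(alpha = 0.05, min_passing = 3,
                             assign_rule = c("max-passing", "max-top3")) {
  stopifnot(alpha > 0, alpha < 1, min_passing >= 1, min_passing <= 4)
  structure(list(alpha = alpha, min_passing = min_passing,
                 assign_rule = match.arg(assign_rule)),
            class = "consensus_policy")
}

#' Call positively selected genes by test consensus
#'
#' @param matrix data.frame with columns `gene`, `pA_gap`, `pA_nogap`,
#'   `pB_gap`, `pB_nogap` (P-values in `[0, 1]`, NA = missing test).
#'   Genes with fewer than `min_passing` non-missing tests are excluded
#'   and listed in the log.
#' @param policy A [consensus_policy()].
#' @return List:
#'   * `calls`: data.frame `gene`, `n_passing`, `psg` (logical),
#'     `assigned_p` (NA unless PSG), sorted by assigned P then gene id
#'     (non-PSGs last, by gene id);
#'   * `excluded`: character vector of genes with too few tests.
#' @export
call_psgs <- function(matrix, policy = consensus_policy()) {
  stopifnot(inherits(policy, "consensus_policy"),
            all(c("gene", psg_test_cols) %in% names(matrix)))
  p <- as.matrix(matrix[, psg_test_cols])
  bad <- which(rowSums(p < 0 | p > 1, na.rm = TRUE) > 0)
  fail_if(length(bad) > 0, "P-value outside [0, 1] for gene %s",
          matrix$gene[bad[1]])
  n_present <- rowSums(!is.na(p))
  excluded <- matrix$gene[n_present < policy$min_passing]
  keep <- n_present >= policy$min_passing
  p <- p[keep, , drop = FALSE]
  genes <- matrix$gene[keep]
  pass <- !is.na(p) & p < policy$alpha
  n_passing <- rowSums(pass)
  is_psg <- n_passing >= policy$min_passing
  assigned <- rep(NA_real_, length(genes))
  for (i in which(is_psg)) {
    pp <- sort(p[i, pass[i, ]])
    assigned[i] <- if (policy$assign_rule == "max-top3")
      max(pp[seq_len(min(3, length(pp)))]) else max(pp)
  }
  calls <- data.frame(gene = genes, n_passing = n_passing, psg = is_psg,
                      assigned_p = assigned, stringsAsFactors = FALSE)
  calls <- calls[order(!calls$psg, calls$assigned_p, calls$gene), , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, excluded = excluded)
}

#' Collapse ohnolog a/b paralog symbols
#'
#' Teleost whole-genome-duplication paralogs are conventionally named
#' with trailing `a`/`b` suffixes (e.g. `cyp19a1a`/`cyp19a1b`). When both
#' suffixed forms of a base symbol (length >= 3) are present and the base
#' symbol itself is not, both are collapsed to the base; every other
#' symbol maps to itself. Case is preserved on the base.
#'
#' @param symbols Character vector of gene symbols.
#' @return List: `collapsed` (unique collapsed symbol set) and `mapping`
#'   (named character vector, input symbol -> collapsed symbol).
#' @export
collapse_paralogs <- function(symbols) {
  stopifnot(is.character(symbols), all(nzchar(symbols)))
  symbols_u <- unique(symbols)
  mapping <- stats::setNames(symbols_u, symbols_u)
  suffix <- substring(symbols_u, nchar(symbols_u))
  base <- substring(symbols_u, 1, nchar(symbols_u) - 1)
  is_ab <- suffix %in% c("a", "b") & nchar(base) >= 3
  for (bs in unique(base[is_ab])) {
    has_a <- paste0(bs, "a") %in% symbols_u
    has_b <- paste0(bs, "b") %in% symbols_u
    if (has_a && has_b && !(bs %in% symbols_u)) {
      mapping[paste0(bs, c("a", "b"))] <- bs
    }
  }
  list(collapsed = unique(unname(mapping[symbols])), mapping = mapping)
}

#' Hypergeometric gene-set enrichment
#'
#' For a query gene set against a background of size N, a term with K
#' background genes and k overlapping query genes out of n gets the
#' upper-tail probability
#' `P = sum_{i >= k} C(K,i) C(N-K, n-i) / C(N,n)`,
#' with Benjamini-Hochberg adjustment across all tested terms.
#'
#' @param query Character vector of query genes (must all be in
#'   `background`).
#' @param term2gene data.frame with columns `term`, `gene`; genes outside
#'   the background are ignored.
#' @param background Character vector: the background gene universe.
#' @return data.frame sorted by `p` then `term`: `term`, `term_size`,
#'   `overlap`, `p`, `q`.
#' @export
hypergeometric_enrichment <- function(query, term2gene, background) {
  stopifnot(all(c("term", "gene") %in% names(term2gene)))
  background <- unique(background)
  query <- unique(query)
  out_of_bg <- setdiff(query, background)
  fail_if(length(out_of_bg) > 0, "query genes outside background: %s",
          paste(out_of_bg, collapse = ", "))
  N <- length(background)
  n <- length(query)
  t2g <- term2gene[term2gene$gene %in% background, , drop = FALSE]
  t2g <- unique(t2g[, c("term", "gene")])
  terms <- sort(unique(t2g$term))
  res <- do.call(rbind, lapply(terms, function(tm) {
    genes <- t2g$gene[t2g$term == tm]
    K <- length(genes)
    k <- length(intersect(genes, query))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term = tm, term_size = K, overlap = k, p = p,
               stringsAsFactors = FALSE)
  }))
  if (is.null(res)) {
    return(data.frame(term = character(0), term_size = integer(0),
                      overlap = integer(0), p = numeric(0), q = numeric(0)))
  }
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$term), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Calibrate the consensus rule on simulated P-value matrices
#'
#' Monte-Carlo estimate of the type-I error (fraction of null genes
#' called) and power (fraction of selected genes called) of the
#' consensus rule, compared with calling from a single test at the same
#' alpha. Under the null the consensus rule's type-I error has the
#' closed form `P(Binomial(4, alpha) >= min_passing)`.
#'
#' @param n_genes Genes per replicate.
#' @param frac_selected Fraction of genes under selection.
#' @param alt_strength Beta shape of the alternative (see
#'   [simulate_psg_table()]).
#' @param reps Number of replicates (>= 1).
#' @param seed Integer seed.
#' @param policy A [consensus_policy()].
#' @return data.frame: `rule` (`consensus`/`single_test`), `metric`
#'   (`type_I_error`/`power`), `estimate`, `se` (Monte-Carlo SE),
#'   `n` (gene draws behind the estimate).
#' @export
consensus_calibration <- function(n_genes, frac_selected = 0,
                                  alt_strength = 0.05, reps = 1, seed = 1,
                                  policy = consensus_policy()) {
  stopifnot(reps >= 1)
  tot <- list(consensus = c(null_called = 0, null_n = 0, sel_called = 0, sel_n = 0),
              single_test = c(null_called = 0, null_n = 0, sel_called = 0, sel_n = 0))
  for (r in seq_len(reps)) {
    tab <- simulate_psg_table(n_genes, frac_selected, alt_strength,
                              seed = seed + r - 1)
    called <- call_psgs(tab, policy)$calls
    psg <- called$psg[match(tab$gene, called$gene)]
    single <- tab$pA_gap < policy$alpha
    for (rule in names(tot)) {
      hit <- if (rule == "consensus") psg else single
      tot[[rule]]["null_called"] <- tot[[rule]]["null_called"] + sum(hit & !tab$selected)
      tot[[rule]]["null_n"] <- tot[[rule]]["null_n"] + sum(!tab$selected)
      tot[[rule]]["sel_called"] <- tot[[rule]]["sel_called"] + sum(hit & tab$selected)
      tot[[rule]]["sel_n"] <- tot[[rule]]["sel_n"] + sum(tab$selected)
    }
  }
  rows <- list()
  for (rule in names(tot)) {
    for (metric in c("type_I_error", "power")) {
      num <- if (metric == "type_I_error") tot[[rule]]["null_called"] else tot[[rule]]["sel_called"]
      den <- if (metric == "type_I_error") tot[[rule]]["null_n"] else tot[[rule]]["sel_n"]
      est <- if (den > 0) num / den else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        rule = rule, metric = metric, estimate = unname(est),
        se = if (den > 0) unname(sqrt(est * (1 - est) / den)) else NA_real_,
        n = unname(den), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
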