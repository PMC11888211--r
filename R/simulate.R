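#' Per-branch substitution rate achieving a target pairwise divergence
#'
#' Two sequences independently mutated from a common ancestor at per-site rate
#' r (uniform over the three other bases) differ at a site with probability
#' `2r - (4/3) r^2`; this inverts that relation.
#'
#' @param d target pairwise divergence in \[0, 0.75).
#' @return per-branch substitution rate.
#' @export
divergence_to_rate <- function(d) {
  if (any(d < 0 | d >= 0.75)) stop("divergence must be in [0, 0.75)")
  (2 - sqrt(4 - (16 / 3) * d)) / (8 / 3)
}

mutate_chars <- function(ch, dfr) {
  sites <- which(ch %in% DNA_BASES4)
  if (dfr > 0 && length(sites)) {
    hit <- sites[runif(length(sites)) < dfr]
    if (length(hit)) {
      cur <- match(ch[hit], DNA_BASES4)
      ch[hit] <- DNA_BASES4[(cur - 1L + sample.int(3L, length(hit),
                                                   replace = TRUE)) %% 4L + 1L]
    }
  }
  ch
}

#' Uniformly mutate a sequence
#'
#' Each non-gap site is independently substituted with probability `dfr`,
#' uniformly to one of the three other bases (never back to itself); gaps are
#' untouched. Randomness comes from the current R random number generator.
#'
#' @param seq character string or character vector of single symbols.
#' @param dfr per-site substitution probability (the simulated difference from
#'   reference).
#' @return mutated sequence, same representation as the input.
#' @export
mutate_sequence <- function(seq, dfr) {
  if (dfr < 0 || dfr >= 1) stop("dfr must be in [0, 1)")
  scalar <- length(seq) == 1L && nchar(seq[1L]) > 1L
  ch <- if (scalar) strsplit(seq, "", fixed = TRUE)[[1L]] else seq
  ch <- mutate_chars(ch, dfr)
  if (scalar) paste(ch, collapse = "") else ch
}

#' Sample a genotype: one allele per gene
#'
#' Mirrors genotype construction from a full allele database: for each gene
#' (the part of the allele name before '*'), one allele is chosen uniformly at
#' random. Deterministic for a fixed seed.
#'
#' @param db FASTA path or named character vector of allele sequences; names
#'   must parse as `gene*allele`.
#' @param seed integer seed.
#' @return named character vector with exactly one allele per gene, in order
#'   of first appearance of each gene.
#' @export
build_genotype <- function(db, seed = 1L) {
  seqs <- if (is.character(db) && length(db) == 1L && file.exists(db)) {
    ss <- Biostrings::readBStringSet(db)
    setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
  } else db
  nm <- names(seqs)
  if (is.null(nm) || any(!grepl("*", nm, fixed = TRUE)))
    stop("allele names must follow the gene*allele convention; offending: ",
         paste(head(nm[!grepl("*", nm, fixed = TRUE)], 3L), collapse = ", "))
  genes <- allele_gene(nm)
  set.seed(seed)
  pick <- vapply(split(seq_along(nm), factor(genes, levels = unique(genes))),
                 function(ix) if (length(ix) == 1L) ix else sample(ix, 1L),
                 integer(1L))
  seqs[pick]
}

#' Generate a family-structured synthetic germline V set
#'
#' Self-contained stand-in for a real germline database: one root sequence per
#' family, drawn so that roots of different families sit at pairwise
#' divergence about `between_div`, then genes within a family at pairwise
#' divergence about `within_div`. Gap-free, so MSA columns coincide with
#' ungapped positions. Allele names follow the `SV<family>-<gene>*01`
#' convention so gene/family extraction works as for IMGT names.
#'
#' @param n_genes total number of genes.
#' @param n_families number of families (genes are split as evenly as
#'   possible).
#' @param within_div,between_div target pairwise divergences in \[0, 0.75).
#' @param L sequence length (columns).
#' @param seed integer seed.
#' @return a `reference_msa`.
#' @export
synth_germline_set <- function(n_genes = 50L, n_families = 7L,
                               within_div = 0.06, between_div = 0.30,
                               L = 300L, seed = 1L) {
  if (n_families > n_genes) stop("more families than genes")
  set.seed(seed)
  root <- sample(DNA_BASES4, L, replace = TRUE)
  rb <- divergence_to_rate(between_div)
  rw <- divergence_to_rate(within_div)
  sizes <- rep(n_genes %/% n_families, n_families)
  extra <- n_genes %% n_families
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  seqs <- character(0)
  for (f in seq_len(n_families)) {
    fam_root <- mutate_chars(root, rb)
    for (g in seq_len(sizes[f])) {
      s <- paste(mutate_chars(fam_root, rw), collapse = "")
      seqs[sprintf("SV%d-%d*01", f, g)] <- s
    }
  }
  as_reference_msa(seqs)
}

#' Simulate a labeled repertoire with a fixed chimerism rate
#'
#' Produces exactly `round(n_total * chimera_rate)` chimeric and the remaining
#' non-chimeric records. A non-chimeric record is one reference mutated at
#' `dfr`; a chimeric record joins two distinct, independently mutated
#' references at a breakpoint drawn uniformly on \[2, L\] (columns before the
#' breakpoint from the left parent, the rest from the right parent). The AIRR
#' table carries perfect alignments against the left parent (`v_call`, start
#' 1), so detection runs without an external aligner — deliberately including
#' the annotation stress that a chimera is threaded via one (partially wrong)
#' parent.
#'
#' @param refs a `reference_msa` (N >= 2 when `chimera_rate > 0`).
#' @param n_total number of records.
#' @param chimera_rate fraction of chimeric records.
#' @param dfr per-site mutation probability applied to every parent.
#' @param seed integer seed; all randomness flows from it.
#' @param out_prefix if given, writes `<prefix>.airr.tsv`,
#'   `<prefix>.truth.tsv` and `<prefix>.refs.fasta`.
#' @return list with `truth` (data.table: sequence_id, is_chimera, parent1,
#'   parent2, breakpoint, dfr, n_mutations), `airr` (data.table with the
#'   required AIRR columns), and `refs`.
#' @export
simulate_dataset <- function(refs, n_total, chimera_rate = 0.05, dfr = 0,
                             seed = 1L, out_prefix = NULL) {
  if (n_total < 1L) stop("n_total must be >= 1")
  if (chimera_rate < 0 || chimera_rate > 1) stop("chimera_rate must be in [0, 1]")
  n_chim <- round(n_total * chimera_rate)
  n_non <- n_total - n_chim
  if (n_chim > 0L && refs$N < 2L)
    stop("chimera simulation needs at least 2 references")
  set.seed(seed)
  L <- refs$L

  sim_seq <- vector("list", n_total)
  is_chim <- c(rep(FALSE, n_non), rep(TRUE, n_chim))
  parent1 <- character(n_total)
  parent2 <- rep(NA_character_, n_total)
  breakpoint <- rep(NA_integer_, n_total)
  n_mut <- integer(n_total)

  for (i in seq_len(n_non)) {
    r <- sample.int(refs$N, 1L)
    ch <- mutate_chars(refs$mat[r, ], dfr)
    sim_seq[[i]] <- ch
    parent1[i] <- refs$names[r]
    n_mut[i] <- sum(ch != refs$mat[r, ])
  }
  for (i in seq_len(n_chim)) {
    j <- n_non + i
    pr <- sample.int(refs$N, 2L)          # two distinct alleles
    bp <- sample(2:L, 1L)
    m1 <- mutate_chars(refs$mat[pr[1L], ], dfr)
    m2 <- mutate_chars(refs$mat[pr[2L], ], dfr)
    ch <- c(m1[seq_len(bp - 1L)], m2[bp:L])
    template <- c(refs$mat[pr[1L], seq_len(bp - 1L)], refs$mat[pr[2L], bp:L])
    sim_seq[[j]] <- ch
    parent1[j] <- refs$names[pr[1L]]
    parent2[j] <- refs$names[pr[2L]]
    breakpoint[j] <- bp
    n_mut[j] <- sum(ch != template)
  }

  ord <- sample.int(n_total)
  ids <- sprintf("sim_%06d", seq_len(n_total))

  seq_aln <- germ_aln <- character(n_total)
  germ_end <- integer(n_total)
  for (o in seq_len(n_total)) {
    i <- ord[o]
    germ <- refs$mat[match(parent1[i], refs$names), ]
    ch <- sim_seq[[i]]
    keep <- !(ch == "-" & germ == "-")
    seq_aln[o] <- paste(ch[keep], collapse = "")
    germ_aln[o] <- paste(germ[keep], collapse = "")
    germ_end[o] <- sum(germ != "-")
  }
  truth <- data.table::data.table(
    sequence_id = ids, is_chimera = is_chim[ord], parent1 = parent1[ord],
    parent2 = parent2[ord], breakpoint = breakpoint[ord], dfr = dfr,
    n_mutations = n_mut[ord])
  airr <- data.table::data.table(
    sequence_id = ids, v_call = parent1[ord],
    v_sequence_alignment = seq_aln, v_germline_alignment = germ_aln,
    v_germline_start = 1L, v_germline_end = germ_end)

  if (!is.null(out_prefix)) {
    data.table::fwrite(airr, paste0(out_prefix, ".airr.tsv"), sep = "\t",
                       quote = FALSE)
    data.table::fwrite(truth, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                       quote = FALSE, logical01 = FALSE)
    write_fasta(setNames(refs$seqs, refs$names),
                paste0(out_prefix, ".refs.fasta"))
  }
  list(truth = truth, airr = airr, refs = refs)
}

#' Evaluate detection against simulation truth
#'
#' AUC is the tie-averaged rank statistic (via pROC); the confusion counts use
#' the `posterior >= threshold` call rule. With single-class truth the AUC is
#' undefined and returned as `NA` with a warning; the counts are still valid.
#'
#' @param posteriors numeric scores.
#' @param is_chimera logical truth labels.
#' @param threshold call threshold.
#' @return list with `auc`, `tpr`, `fpr`, `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate_detection <- function(posteriors, is_chimera, threshold = 0.95) {
  if (length(posteriors) != length(is_chimera))
    stop("posteriors and truth labels differ in length")
  is_chimera <- as.logical(is_chimera)
  call <- posteriors >= threshold
  tp <- sum(call & is_chimera); fp <- sum(call & !is_chimera)
  tn <- sum(!call & !is_chimera); fn <- sum(!call & is_chimera)
  auc <- if (length(unique(is_chimera)) < 2L) {
    warning("AUC undefined: truth labels contain a single class")
    NA_real_
  } else {
    as.numeric(pROC::auc(pROC::roc(
      response = is_chimera, predictor = posteriors,
      levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
  }
  list(auc = auc,
       tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       fpr = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}
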