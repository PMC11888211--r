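#' Receptor preset
#'
#' Immunoglobulin (IG) data carries somatic hypermutation, so the preset is BW
#' mode with rates initialized at 0.05; T-cell receptor (TR) data only carries
#' sequencing error, so the preset is DB mode with a single fixed 0.005 rate.
#'
#' @param receptor "IG" or "TR".
#' @return list with `receptor`, `method`, and the method's parameters.
#' @export
receptor_preset <- function(receptor = c("IG", "TR")) {
  receptor <- match.arg(toupper(receptor), c("IG", "TR"))
  if (receptor == "IG")
    list(receptor = "IG", method = "BW", init_rate = 0.05)
  else
    list(receptor = "TR", method = "DB", mutation_rate = 0.005)
}

#' End-to-end chimera detection
#'
#' Reads the reference MSA and the AIRR file, threads every query onto the MSA
#' coordinate system, scores it with the chimera HMM (per-query Forward pass
#' in DB mode; dataset-level Baum-Welch fit then per-query posteriors in BW
#' mode), calls chimeras at the posterior threshold, optionally segments them
#' with Viterbi, and writes the annotated AIRR file.
#'
#' @param airr_path AIRR Rearrangement TSV.
#' @param msa_path FASTA of the aligned germline V database.
#' @param out_path output TSV.
#' @param receptor optional "IG" or "TR" preset; explicit arguments override
#'   preset values.
#' @param method "DB" or "BW" (default "DB" when no preset is given).
#' @param mutation_rate single fixed rate for DB mode; when `NULL`, DB uses the
#'   `k`-class grid on \[`min_rate`, `max_rate`\].
#' @param k,min_rate,max_rate DB rate grid (defaults: 15 classes on \[0, 0.25\]).
#' @param init_rate BW initialization.
#' @param psi,mu per-column switching rates (reference / rate class).
#' @param threshold posterior call threshold.
#' @param viterbi_all run Viterbi for every query, not only called chimeras.
#' @param recomb_path optional path for the left-gene x right-gene
#'   recombination count table of single-recombination chimeras.
#' @param strict fail on queries whose v_call allele is absent from the MSA
#'   instead of skipping them.
#' @param max_iter,tol BW stopping rule.
#' @return (invisibly) counts: `total`, `analyzed`, `skipped`, `chimeric`.
#' @export
detect <- function(airr_path, msa_path, out_path,
                   receptor = NULL, method = NULL, mutation_rate = NULL,
                   k = 15L, min_rate = 0, max_rate = 0.25,
                   init_rate = 0.05, psi = 1e-4, mu = 1e-3,
                   threshold = 0.95, viterbi_all = FALSE,
                   recomb_path = NULL, strict = FALSE,
                   max_iter = 10L, tol = 1e-3) {
  msa <- read_reference_msa(msa_path)
  airr <- read_airr(airr_path)
  total <- nrow(airr) + attr(airr, "skipped_empty")
  if (!is.null(receptor)) {
    preset <- receptor_preset(receptor)
    if (is.null(method)) method <- preset$method
    if (method == "DB" && is.null(mutation_rate) &&
        !is.null(preset$mutation_rate))
      mutation_rate <- preset$mutation_rate
  }
  if (is.null(method)) method <- "DB"
  method <- match.arg(method, c("DB", "BW"))

  th <- thread_queries(airr, msa, strict = strict)
  if (length(th$kept) == 0L) stop("no analyzable queries in ", airr_path)
  airr <- airr[th$kept]

  if (method == "DB") {
    rates <- if (!is.null(mutation_rate)) as.numeric(mutation_rate)
             else db_rate_grid(k, min_rate, max_rate)
    mu_eff <- if (length(rates) == 1L) 0 else mu
    config <- model_config(psi = psi, mu = mu_eff, rates = rates,
                           method = "DB", threshold = threshold)
    res <- cpp_forward_batch(th$obs_codes, msa$codes,
                             rates_matrix(config, msa$N), psi, mu_eff)
    posteriors <- res$posterior
  } else {
    fit <- fit_bw(th$obs_codes, msa,
                  bw_config(init_rate = init_rate, max_iter = max_iter,
                            tol = tol), psi = psi)
    posteriors <- fit$posteriors
    config <- model_config(psi = psi, mu = 0, rates = init_rate,
                           method = "BW", threshold = threshold,
                           rate_matrix = matrix(fit$rates, ncol = 1L))
  }
  calls <- posteriors >= threshold

  segments <- breakpoints <- rep("", length(calls))
  vres <- list()
  run_vit <- if (viterbi_all) seq_along(calls) else which(calls)
  if (length(run_vit)) {
    space <- build_state_space(msa, config)
    for (i in run_vit) {
      v <- viterbi_linear(th$obs_codes[, i], msa, config, space)
      vres[[length(vres) + 1L]] <- v
      segments[i] <- paste(sprintf("%s:%d-%d", v$segments$reference,
                                   v$segments$start, v$segments$end),
                           collapse = ";")
      breakpoints[i] <- paste(v$breakpoints, collapse = ";")
    }
  }
  call_tab <- data.frame(posterior = posteriors, chimera = calls,
                         segments = segments, breakpoints = breakpoints,
                         stringsAsFactors = FALSE)
  if (!length(run_vit)) call_tab$segments <- call_tab$breakpoints <- NULL
  write_detect_output(airr, call_tab, out_path)

  if (!is.null(recomb_path)) {
    tab <- tabulate_recombinations(vres)
    data.table::fwrite(tab, recomb_path, sep = "\t", quote = FALSE)
  }
  counts <- list(total = total, analyzed = length(calls),
                 skipped = total - length(calls), chimeric = sum(calls))
  message(sprintf("detect: %d read, %d analyzed, %d skipped, %d chimeric",
                  counts$total, counts$analyzed, counts$skipped,
                  counts$chimeric))
  invisible(counts)
}

allele_gene <- function(x) sub("\\*.*$", "", x)
gene_family <- function(x) sub("-.*$", "", x)

#' Tabulate single-recombination chimeras by gene pair
#'
#' Only segmentations with exactly one reference-changing breakpoint
#' contribute; the key is (gene of the left parent, gene of the right parent),
#' with gene = allele name truncated at '*'.
#'
#' @param viterbi_results list of `viterbi_result` objects.
#' @return a `recombination_table`: data.table with `left_gene`, `right_gene`,
#'   `count`.
#' @export
tabulate_recombinations <- function(viterbi_results) {
  pairs <- lapply(viterbi_results, function(v) {
    runs <- rle(v$segments$reference)$values
    if (length(runs) != 2L) return(NULL)
    data.table::data.table(left_gene = allele_gene(runs[1L]),
                           right_gene = allele_gene(runs[2L]))
  })
  pairs <- data.table::rbindlist(pairs)
  if (nrow(pairs) == 0L) {
    tab <- data.table::data.table(left_gene = character(),
                                  right_gene = character(),
                                  count = integer())
  } else {
    tab <- pairs[, list(count = .N), by = c("left_gene", "right_gene")]
    data.table::setorder(tab, left_gene, right_gene)
  }
  structure(tab, class = c("recombination_table", class(tab)))
}

#' Fraction of recombination count mass within the same gene family
#'
#' The family is the token before the first '-' of the gene name (IMGT
#' convention, e.g. IGHV1 for IGHV1-2); genes without '-' form their own
#' family.
#'
#' @param table a `recombination_table`.
#' @return fraction in \[0, 1\].
#' @export
same_family_fraction <- function(table) {
  if (nrow(table) == 0L || sum(table$count) == 0L)
    stop("empty recombination table")
  same <- gene_family(table$left_gene) == gene_family(table$right_gene)
  sum(table$count[same]) / sum(table$count)
}
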