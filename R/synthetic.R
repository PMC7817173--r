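## Seeded generators for pulse-chase division tables and pooled-screen
## count tables.  These emulate the sampling structure of the assays
## (multinomial fate draws per animal; negative-binomial hairpin counts
## per sorted compartment) so every estimator in the package can be
## exercised and calibrated without external data.

#' Sample a synthetic pulse-chase (CFI) division-event table
#'
#' Draws division types from a multinomial at the given fate fractions,
#' independently per animal, and emits each division as an EdU-only
#' doublet with daughter layers consistent with its type.  A fraction of
#' the label-window cohort has already divided by the chase and would be
#' double-labelled and excluded from scoring; the expected number of such
#' excluded cells is attached as attribute `"n_excluded_predivided"`.
#'
#' @param fractions Numeric triplet `(f_SR, f_AD, f_SD)` or a
#'   [fate_fractions()] object.
#' @param n_divisions Scored divisions per animal.
#' @param n_animals Number of animals.
#' @param context,week Values recorded in the event table.
#' @param frac_predivided Fraction of labelled cells already divided at
#'   the chase time (default 0.15).
#' @param seed Mandatory RNG seed.
#' @return A division-event table (see [read_division_table()]).
#' @examples
#' ev <- sample_cfi_dataset(c(0.48, 0.42, 0.10), 75, n_animals = 3, seed = 2)
#' estimate_fate_fractions(ev)
#' @export
sample_cfi_dataset <- function(fractions, n_divisions, n_animals = 1,
                               context = "single_cell", week = 0,
                               frac_predivided = 0.15, seed) {
  if (missing(seed)) stop("sample_cfi_dataset requires an explicit seed",
                          call. = FALSE)
  if (inherits(fractions, "fate_fractions"))
    fractions <- c(fractions$f_SR, fractions$f_AD, fractions$f_SD)
  fractions <- as.numeric(fractions)
  if (length(fractions) != 3L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-8)
    stop("fractions must be a non-negative triplet summing to 1",
         call. = FALSE)
  stopifnot(n_divisions >= 1, n_animals >= 1,
            frac_predivided >= 0, frac_predivided < 1)
  set.seed(seed)
  types <- unlist(lapply(seq_len(n_animals), function(a) {
    sample(c("SR", "AD", "SD"), n_divisions, replace = TRUE,
           prob = fractions)
  }))
  out <- data.frame(
    animal_id = rep(sprintf("animal%02d", seq_len(n_animals)),
                    each = n_divisions),
    clone_id = NA_character_, context = context, week = week,
    daughter1_layer = ifelse(types == "SD", "suprabasal", "basal"),
    daughter2_layer = ifelse(types == "SR", "basal", "suprabasal"),
    daughter1_morph = "unknown", daughter2_morph = "unknown",
    stringsAsFactors = FALSE)
  attr(out, "n_excluded_predivided") <-
    round(nrow(out) * frac_predivided / (1 - frac_predivided))
  out
}

#' Design table for a pooled shRNA screen simulation
#'
#' The default mirrors the screen's library layout: 28 target genes with
#' 4-5 hairpins each, 135 constructs in total (23 genes x 5 + 5 genes x
#' 4), and no true basal/suprabasal effect.
#'
#' @param n_genes Number of target genes.
#' @param shrnas_per_gene Either a single count or a vector of per-gene
#'   counts; the default splits 5 and 4 hairpins to reach 135 constructs.
#' @param gene_effects Named numeric vector of true log2 basal/suprabasal
#'   enrichments applied to every hairpin of the named genes.
#' @return Data frame `gene`, `shrna_id`, `log2_effect`.
#' @examples
#' d <- screen_design(gene_effects = c(gene01 = 1.5))
#' table(d$log2_effect)
#' @export
screen_design <- function(n_genes = 28, shrnas_per_gene = NULL,
                          gene_effects = NULL) {
  if (is.null(shrnas_per_gene)) {
    shrnas_per_gene <- c(rep(5L, max(0L, n_genes - 5L)),
                         rep(4L, min(5L, n_genes)))
  } else if (length(shrnas_per_gene) == 1L) {
    shrnas_per_gene <- rep(as.integer(shrnas_per_gene), n_genes)
  }
  stopifnot(length(shrnas_per_gene) == n_genes, all(shrnas_per_gene >= 1))
  gene <- rep(sprintf("gene%02d", seq_len(n_genes)), shrnas_per_gene)
  idx <- unlist(lapply(shrnas_per_gene, seq_len))
  eff <- rep(0, length(gene))
  if (!is.null(gene_effects)) {
    bad <- setdiff(names(gene_effects), unique(gene))
    if (length(bad)) stop("unknown gene(s) in gene_effects: ",
                          paste(bad, collapse = ", "), call. = FALSE)
    eff <- unname(ifelse(gene %in% names(gene_effects),
                         gene_effects[gene], 0))
  }
  data.frame(gene = gene, shrna_id = paste0(gene, "_sh", idx),
             log2_effect = eff, stringsAsFactors = FALSE)
}

#' Simulate pooled shRNA screen counts
#'
#' Negative-binomial hairpin counts for the basal (alpha6-integrin high)
#' and suprabasal (alpha6-integrin low) sorted compartments, with planted
#' per-hairpin log2 enrichments from the design and library-size
#' variation between replicates.
#'
#' @param design A [screen_design()] data frame (columns `gene`,
#'   `shrna_id`, `log2_effect`).
#' @param n_replicates Animals per compartment.
#' @param dispersion Negative-binomial dispersion (variance
#'   `mu + dispersion * mu^2`).
#' @param lib_size Mean library size per replicate.
#' @param abundance_sdlog Log-sd of the baseline hairpin abundances.
#' @param libsize_sdlog Log-sd of the replicate library sizes.
#' @param seed Mandatory RNG seed.
#' @return A count table (see [read_count_table()]).
#' @examples
#' counts <- simulate_screen_counts(screen_design(), seed = 5)
#' head(counts)
#' @export
simulate_screen_counts <- function(design = screen_design(),
                                   n_replicates = 3, dispersion = 0.15,
                                   lib_size = 1e6, abundance_sdlog = 0.5,
                                   libsize_sdlog = 0.2, seed) {
  if (missing(seed)) stop("simulate_screen_counts requires an explicit seed",
                          call. = FALSE)
  stopifnot(is.data.frame(design),
            all(c("gene", "shrna_id", "log2_effect") %in% names(design)),
            n_replicates >= 1, dispersion > 0)
  if (any(lib_size <= 0)) stop("library size must be positive", call. = FALSE)
  set.seed(seed)
  ns <- nrow(design)
  w <- stats::rlnorm(ns, meanlog = 0, sdlog = abundance_sdlog)
  wb <- w * 2^(design$log2_effect / 2)
  ws <- w * 2^(-design$log2_effect / 2)
  out <- vector("list", 2L * n_replicates)
  k <- 0L
  for (comp in c("basal", "suprabasal")) {
    share <- if (comp == "basal") wb / sum(wb) else ws / sum(ws)
    for (rep_i in seq_len(n_replicates)) {
      lib <- lib_size * stats::rlnorm(1, 0, libsize_sdlog)
      mu <- lib * share
      k <- k + 1L
      out[[k]] <- data.frame(
        gene = design$gene, shrna_id = design$shrna_id,
        compartment = comp, replicate = sprintf("rep%d", rep_i),
        count = stats::rnbinom(ns, mu = mu, size = 1 / dispersion),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
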