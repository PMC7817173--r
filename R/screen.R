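## Pooled shRNA screen: basal/suprabasal enrichment and gene hit calling.
##
## Hairpins enriched in the basal (alpha6-integrin high) compartment mark
## genes whose loss inhibits differentiation (negative regulators of
## renewal); suprabasal enrichment marks depleted renewal promoters.
## A gene is a hit only when at least two of its hairpins are
## significantly enriched in the same direction.

.check_count_table <- function(counts) {
  stopifnot(is.data.frame(counts))
  need <- c("gene", "shrna_id", "compartment", "replicate", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss))
    stop("count table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(counts$count < 0) || any(counts$count != round(counts$count)))
    stop("counts must be non-negative integers", call. = FALSE)
  invisible(counts)
}

.count_matrix <- function(counts) {
  lib <- paste(counts$compartment, counts$replicate, sep = ".")
  m <- stats::xtabs(count ~ shrna_id + lib,
                    data = cbind(counts, lib = lib))
  m <- matrix(as.numeric(m), nrow(m), ncol(m), dimnames = dimnames(m))
  m
}

#' Median-of-ratios library normalization
#'
#' Computes one size factor per (compartment, replicate) library by the
#' median-of-ratios method: each library's counts are divided by the
#' per-hairpin geometric mean across libraries (over hairpins observed in
#' every library) and the library's median ratio becomes its size factor.
#' Normalized counts are appended as a `norm_count` column.
#'
#' @param counts Count table (see [read_count_table()]).
#' @return The table with an extra `norm_count` column and the size
#'   factors as attribute `"size_factors"`.
#' @examples
#' counts <- simulate_screen_counts(seed = 3)
#' attr(normalize_counts(counts), "size_factors")
#' @export
normalize_counts <- function(counts) {
  .check_count_table(counts)
  m <- .count_matrix(counts)
  if (any(colSums(m) == 0))
    stop("all-zero library: ",
         paste(colnames(m)[colSums(m) == 0], collapse = ", "), call. = FALSE)
  pos <- rowSums(m > 0) == ncol(m)
  if (!any(pos))
    stop("no hairpin observed in every library; cannot normalize",
         call. = FALSE)
  loggeo <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(col) {
    exp(stats::median(log(col) - loggeo))
  })
  lib <- paste(counts$compartment, counts$replicate, sep = ".")
  counts$norm_count <- counts$count / sf[lib]
  attr(counts, "size_factors") <- sf
  counts
}

#' Per-hairpin basal/suprabasal enrichment test
#'
#' For every hairpin, the log2 ratio of mean normalized basal to
#' suprabasal counts (pseudocount 0.5 added before the ratio) is tested
#' either by a negative-binomial Wald test with method-of-moments
#' dispersion (`nb_wald`; per-hairpin estimates floored by the
#' screen-wide median so a lucky tight triplet cannot fake precision) or
#' by permutation of compartment labels (`permutation`; exact enumeration
#' when feasible).  p-values are Benjamini-Hochberg adjusted across all
#' hairpins.
#'
#' @param counts Count table; normalized on the fly if `norm_count` is
#'   absent.
#' @param method `"nb_wald"` or `"permutation"`.
#' @param q_threshold Significance threshold used to set the reported
#'   `direction`.
#' @param pseudocount Added to mean normalized counts before the log
#'   ratio.
#' @param n_perm Permutation-count cap for the permutation method (exact
#'   enumeration is used when the number of label assignments is below
#'   this).
#' @param seed Seed for sampled permutations (required only when
#'   enumeration is infeasible).
#' @return Data frame of class `enrichment_result`: `gene`, `shrna_id`,
#'   `log2_ratio`, `p_value`, `q_value`, `direction`
#'   (`"basal"`/`"suprabasal"`/`"none"`).
#' @examples
#' counts <- simulate_screen_counts(
#'   screen_design(gene_effects = c(gene01 = 2)), seed = 4)
#' res <- shrna_enrichment(counts)
#' head(res[order(res$q_value), ])
#' @export
shrna_enrichment <- function(counts, method = c("nb_wald", "permutation"),
                             q_threshold = 0.05, pseudocount = 0.5,
                             n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  if (!"norm_count" %in% names(counts)) counts <- normalize_counts(counts)
  .check_count_table(counts)
  is_b <- counts$compartment == "basal"
  if (!any(is_b) || all(is_b))
    stop("count table must contain both compartments", call. = FALSE)
  sh <- unique(counts$shrna_id)
  gene <- counts$gene[match(sh, counts$shrna_id)]
  bl <- split(counts$norm_count[is_b], counts$shrna_id[is_b])[sh]
  sl <- split(counts$norm_count[!is_b], counts$shrna_id[!is_b])[sh]
  m_b <- lengths(bl); m_s <- lengths(sl)
  if (method == "nb_wald" && (any(m_b < 2) || any(m_s < 2)))
    stop("nb_wald needs at least two replicates per compartment",
         call. = FALSE)
  if (method == "permutation" && (any(m_b < 3) || any(m_s < 3)))
    stop("permutation needs at least three replicates per compartment",
         call. = FALSE)

  mean_b <- vapply(bl, mean, numeric(1)) + pseudocount
  mean_s <- vapply(sl, mean, numeric(1)) + pseudocount
  lfc <- log2(mean_b / mean_s)

  if (method == "nb_wald") {
    mom <- function(v) {
      mu <- mean(v)
      if (mu <= 0) return(NA_real_)
      max((stats::var(v) - mu) / mu^2, 0)
    }
    a_b <- vapply(bl, mom, numeric(1))
    a_s <- vapply(sl, mom, numeric(1))
    a_i <- rowMeans(cbind(a_b, a_s), na.rm = TRUE)
    a_common <- stats::median(a_i, na.rm = TRUE)
    if (!is.finite(a_common)) a_common <- 0.01
    alpha <- pmax(a_i, a_common, 0.01)
    alpha[!is.finite(alpha)] <- max(a_common, 0.01)
    v_b <- (mean_b + alpha * mean_b^2) / m_b
    v_s <- (mean_s + alpha * mean_s^2) / m_s
    se <- sqrt(v_b / mean_b^2 + v_s / mean_s^2) / log(2)
    z <- lfc / se
    p <- 2 * stats::pnorm(-abs(z))
  } else {
    libs_b <- unique(counts$replicate[is_b])
    libs_s <- unique(counts$replicate[!is_b])
    m <- length(libs_b) + length(libs_s)
    n_exact <- choose(m, length(libs_b))
    if (n_exact <= n_perm) {
      assign_idx <- utils::combn(m, length(libs_b), simplify = FALSE)
    } else {
      if (is.null(seed))
        stop("seed required for sampled permutations", call. = FALSE)
      set.seed(seed)
      assign_idx <- lapply(seq_len(n_perm), function(i)
        sample.int(m, length(libs_b)))
    }
    p <- vapply(seq_along(sh), function(i) {
      v <- c(bl[[i]], sl[[i]])
      stat <- vapply(assign_idx, function(ix) {
        log2((mean(v[ix]) + pseudocount) /
               (mean(v[-ix]) + pseudocount))
      }, numeric(1))
      mean(abs(stat) >= abs(lfc[i]) - 1e-12)
    }, numeric(1))
  }
  q <- stats::p.adjust(p, method = "BH")
  direction <- ifelse(q <= q_threshold & lfc > 0, "basal",
               ifelse(q <= q_threshold & lfc < 0, "suprabasal", "none"))
  structure(data.frame(gene = gene, shrna_id = sh, log2_ratio = unname(lfc),
                       p_value = unname(p), q_value = unname(q),
                       direction = direction, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("enrichment_result", "data.frame"),
            q_threshold = q_threshold, method = method)
}

#' Gene-level hit calls from hairpin enrichment results
#'
#' A gene is called a `basal_hit` (or `suprabasal_hit`) when at least
#' `min_consistent` of its hairpins are significant at `q_threshold` with
#' that direction and no significant hairpin points the other way; any
#' mixed-direction significance yields `no_call`.
#'
#' @param results A [shrna_enrichment()] result.
#' @param min_consistent Minimum number of concordant significant
#'   hairpins (default 2).
#' @param q_threshold BH-adjusted significance threshold (default 0.05).
#' @return Data frame: `gene`, `n_significant_consistent`, `call`,
#'   `supporting_shrnas` (comma-separated ids).
#' @export
call_gene_hits <- function(results, min_consistent = 2, q_threshold = 0.05) {
  stopifnot(is.data.frame(results),
            all(c("gene", "shrna_id", "log2_ratio", "q_value") %in%
                  names(results)))
  out <- lapply(split(results, results$gene), function(g) {
    sig <- g$q_value <= q_threshold
    nb <- sum(sig & g$log2_ratio > 0)
    ns <- sum(sig & g$log2_ratio < 0)
    if (nb >= min_consistent && ns == 0L) {
      call <- "basal_hit"; n <- nb
      sup <- g$shrna_id[sig & g$log2_ratio > 0]
    } else if (ns >= min_consistent && nb == 0L) {
      call <- "suprabasal_hit"; n <- ns
      sup <- g$shrna_id[sig & g$log2_ratio < 0]
    } else {
      call <- "no_call"; n <- 0L; sup <- character(0)
    }
    data.frame(gene = g$gene[1], n_significant_consistent = n, call = call,
               supporting_shrnas = paste(sup, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
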