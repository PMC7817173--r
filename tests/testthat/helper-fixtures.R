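# Shared builders for synthetic test data (everything is generated in
# code; no fixture files).

# division-event table with the given per-type counts, in fixed order
make_events <- function(n_SR, n_AD, n_SD, context = "single_cell",
                        week = 0, animal = "a1") {
  types <- rep(c("SR", "AD", "SD"), c(n_SR, n_AD, n_SD))
  data.frame(
    animal_id = animal, clone_id = NA_character_, context = context,
    week = week,
    daughter1_layer = ifelse(types == "SD", "suprabasal", "basal"),
    daughter2_layer = ifelse(types == "SR", "basal", "suprabasal"),
    daughter1_morph = "unknown", daughter2_morph = "unknown",
    stringsAsFactors = FALSE)
}

# random division-event table (uniform over the three types)
random_events <- function(n, seed) {
  set.seed(seed)
  l <- matrix(sample(c("basal", "suprabasal"), 2 * n, replace = TRUE),
              ncol = 2)
  data.frame(
    animal_id = sample(paste0("a", 1:3), n, replace = TRUE),
    clone_id = NA_character_,
    context = sample(c("single_cell", "clone_edge", "clone_inner"), n,
                     replace = TRUE),
    week = sample(0:24, n, replace = TRUE),
    daughter1_layer = l[, 1], daughter2_layer = l[, 2],
    daughter1_morph = "unknown", daughter2_morph = "unknown",
    stringsAsFactors = FALSE)
}

# random basal cell table with marker flags
random_cells <- function(n, seed, p_edu = 0.4, p_k10 = 0.3) {
  set.seed(seed)
  data.frame(
    animal_id = "a1",
    clone_id = sample(c("c1", NA), n, replace = TRUE),
    cell_id = sprintf("cell%03d", seq_len(n)),
    x_um = runif(n, 0, 100), y_um = runif(n, 0, 100),
    layer = sample(c("basal", "suprabasal"), n, replace = TRUE,
                   prob = c(0.8, 0.2)),
    genotype = "WT",
    edu = rbinom(n, 1, p_edu), brdu = 0L, k10 = rbinom(n, 1, p_k10),
    stringsAsFactors = FALSE)
}

# brute-force threshold graph over basal cells: all pairs within cutoff
brute_force_pairs <- function(cells, cutoff) {
  b <- cells[tolower(cells$layer) == "basal", , drop = FALSE]
  out <- list()
  n <- nrow(b)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d <- sqrt((b$x_um[i] - b$x_um[j])^2 + (b$y_um[i] - b$y_um[j])^2)
    if (d <= cutoff)
      out[[length(out) + 1L]] <- sort(c(b$cell_id[i], b$cell_id[j]))
  }
  if (!length(out)) return(character(0))
  sort(vapply(out, paste, character(1), collapse = "|"))
}

# canonical sorted edge-key representation of a neighbor graph
graph_edge_keys <- function(g) {
  if (!nrow(g$edges)) return(character(0))
  sort(apply(cbind(pmin(g$edges$from, g$edges$to),
                   pmax(g$edges$from, g$edges$to)), 1, paste,
             collapse = "|"))
}
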