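## Delimited-table IO with schema validation.
##
## Column names are the contract (order-free); TSV is the default dialect
## and comma-separated files are accepted.  Enumerated columns are
## normalized case-insensitively; 0/1 and TRUE/FALSE are both accepted
## for marker flags.

.schemas <- list(
  division_event = list(
    required = c("animal_id", "clone_id", "context", "week",
                 "daughter1_layer", "daughter2_layer", "daughter1_morph",
                 "daughter2_morph"),
    enums = list(
      context = c("single_cell", "clone_edge", "clone_inner", "wt_adjacent",
                  "wt_distant", "field"),
      daughter1_layer = c("basal", "suprabasal"),
      daughter2_layer = c("basal", "suprabasal"),
      daughter1_morph = c("cuboidal", "squamous", "unknown"),
      daughter2_morph = c("cuboidal", "squamous", "unknown")),
    numeric = "week", bools = character(0)),
  cell = list(
    required = c("animal_id", "clone_id", "cell_id", "x_um", "y_um",
                 "layer", "genotype", "edu", "brdu", "k10"),
    enums = list(layer = c("basal", "suprabasal"),
                 genotype = c("WT", "HrasG12V", "other")),
    numeric = c("x_um", "y_um"), bools = c("edu", "brdu", "k10")),
  count = list(
    required = c("gene", "shrna_id", "compartment", "replicate", "count"),
    enums = list(compartment = c("basal", "suprabasal")),
    numeric = "count", bools = character(0)))

.schema_chars <- list(
  division_event = c("animal_id", "clone_id"),
  cell = c("animal_id", "clone_id", "cell_id", "genotype"),
  count = c("gene", "shrna_id", "replicate"))

.validate_table <- function(tab, schema_name) {
  sch <- .schemas[[schema_name]]
  miss <- setdiff(sch$required, names(tab))
  if (length(miss))
    stop(schema_name, " table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  for (col in .schema_chars[[schema_name]])
    tab[[col]] <- as.character(tab[[col]])
  for (col in names(sch$enums)) {
    allowed <- sch$enums[[col]]
    v <- trimws(as.character(tab[[col]]))
    hit <- match(tolower(v), tolower(allowed))
    bad <- which(is.na(hit) & !is.na(v) & v != "" & v != "NA")
    if (length(bad))
      stop(schema_name, " table, column '", col, "': invalid value '",
           v[bad[1]], "' at row ", bad[1], call. = FALSE)
    tab[[col]] <- ifelse(is.na(hit), NA_character_, allowed[hit])
  }
  for (col in sch$numeric) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(v))
    if (length(bad))
      stop(schema_name, " table, column '", col,
           "': non-finite or non-numeric value at row ", bad[1],
           call. = FALSE)
    tab[[col]] <- v
  }
  for (col in sch$bools) {
    v <- tolower(trimws(as.character(tab[[col]])))
    hit <- v %in% c("1", "true") - (!v %in% c("0", "1", "true", "false"))
    bad <- which(hit < 0)
    if (length(bad))
      stop(schema_name, " table, column '", col,
           "': expected 0/1 or TRUE/FALSE, got '", tab[[col]][bad[1]],
           "' at row ", bad[1], call. = FALSE)
    tab[[col]] <- as.integer(hit)
  }
  tab
}

.read_delim_auto <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  if (length(header) == 0L) stop("empty file: ", path, call. = FALSE)
  sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                    stringsAsFactors = FALSE, comment.char = "",
                    na.strings = c("NA", ""), check.names = TRUE)
}

#' Read and validate a division-event table
#'
#' Expects a delimited text file (tab or comma separated, header
#' required) with columns `animal_id, clone_id, context, week,
#' daughter1_layer, daughter2_layer, daughter1_morph, daughter2_morph`.
#' Enumerated values are matched case-insensitively and normalized;
#' malformed rows raise an error naming the row and column.
#'
#' @param path Path to the file.
#' @return A validated data frame.
#' @export
read_division_table <- function(path) {
  .validate_table(.read_delim_auto(path), "division_event")
}

#' Read and validate a cell table
#'
#' Columns: `animal_id, clone_id, cell_id, x_um, y_um, layer, genotype,
#' edu, brdu, k10` (marker flags as 0/1 or TRUE/FALSE).  Coordinates must
#' be finite.
#'
#' @param path Path to the file.
#' @return A validated data frame; flags are returned as 0/1 integers.
#' @export
read_cell_table <- function(path) {
  .validate_table(.read_delim_auto(path), "cell")
}

#' Read and validate an shRNA count table
#'
#' Columns: `gene, shrna_id, compartment, replicate, count` with
#' `compartment` one of basal/suprabasal and integer counts.
#'
#' @param path Path to the file.
#' @return A validated data frame.
#' @export
read_count_table <- function(path) {
  tab <- .validate_table(.read_delim_auto(path), "count")
  if (any(tab$count < 0) || any(tab$count != round(tab$count)))
    stop("count table: counts must be non-negative integers",
         call. = FALSE)
  tab
}

#' Write a table as TSV
#'
#' Tab-separated, header, no quoting or row names: the exact dialect the
#' readers accept, so `read(write(x))` round-trips.
#'
#' @param tab Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Built-in deterministic fixture datasets
#'
#' Small seeded datasets used in examples and tests:
#' * `cfi_events` -- division-event table with exact printed-count
#'   composition: 100 control divisions (29 SR / 44 AD / 27 SD) across
#'   animals `wt1..wt3` and 100 oncogenic divisions (48 / 42 / 10) across
#'   `hras1..hras3`, so the renewal-rate anchors (0.51 and 0.69) are
#'   reproduced exactly.
#' * `clone_cells` -- a 7-cell hexagonal rosette clone with one ring of
#'   wild-type neighbors, plus a radius-3 disc clone, on one sheet.
#' * `screen_counts` -- a simulated 135-construct screen with a planted
#'   basal enrichment (`gene01`, +1.5) and a planted suprabasal depletion
#'   (`gene02`, -1.5).
#'
#' @param kind One of `"cfi_events"`, `"clone_cells"`, `"screen_counts"`.
#' @param seed RNG seed for the stochastic fixtures.
#' @return A data frame in the matching schema.
#' @examples
#' ev <- make_fixtures("cfi_events")
#' f <- estimate_fate_fractions(ev, predicate = function(d)
#'   startsWith(d$animal_id, "hras"))
#' renewal_rate_from_fractions(f)
#' @export
make_fixtures <- function(kind = c("cfi_events", "clone_cells",
                                   "screen_counts"), seed = 1) {
  kind <- match.arg(kind)
  if (kind == "cfi_events") {
    build <- function(counts, prefix) {
      types <- rep(c("SR", "AD", "SD"), counts)
      n <- length(types)
      data.frame(
        animal_id = paste0(prefix, rep_len(1:3, n)),
        clone_id = NA_character_, context = "single_cell", week = 0,
        daughter1_layer = ifelse(types == "SD", "suprabasal", "basal"),
        daughter2_layer = ifelse(types == "SR", "basal", "suprabasal"),
        daughter1_morph = "unknown", daughter2_morph = "unknown",
        stringsAsFactors = FALSE)
    }
    rbind(build(c(29L, 44L, 27L), "wt"), build(c(48L, 42L, 10L), "hras"))
  } else if (kind == "clone_cells") {
    rosette <- hex_disc_clone(1, clone_id = "rosette", wt_ring = 1)
    disc <- hex_disc_clone(3, clone_id = "disc3", wt_ring = 1)
    disc$x_um <- disc$x_um + 200
    disc$cell_id <- sub("^c", "d", disc$cell_id)
    rbind(rosette, disc)
  } else {
    simulate_screen_counts(
      screen_design(gene_effects = c(gene01 = 1.5, gene02 = -1.5)),
      seed = seed)
  }
}
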