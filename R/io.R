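# Readers and writers for the tabular formats the pipeline consumes.
# On-disk OTU tables follow the classic QIIME dialect (rows = OTUs,
# columns = samples); in memory the orientation is samples x OTUs so that
# per-sample operations are row operations.

#' Write / read an OTU count table
#'
#' Files store OTUs as rows under a `#OTU ID` leading column; counts must be
#' non-negative integers. Reading validates the matrix and fails loudly,
#' naming the offending OTU and sample, rather than coercing.
#'
#' @param otu integer matrix, samples x OTUs, with dimnames.
#' @param path file path.
#' @return `read_otu_table()` returns the samples x OTUs integer matrix.
#' @export
write_otu_table <- function(otu, path) {
  check_otu_matrix(otu)
  df <- data.frame(`#OTU ID` = colnames(otu), t(otu),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_otu_table
#' @export
read_otu_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (ncol(df) < 2 || names(df)[1] != "#OTU ID") {
    stop("OTU table must start with a '#OTU ID' column", call. = FALSE)
  }
  otu_ids <- as.character(df[[1]])
  stop_if_duplicates(otu_ids, "OTU ids")
  sample_ids <- names(df)[-1]
  stop_if_duplicates(sample_ids, "sample ids")
  m <- as.matrix(df[, -1, drop = FALSE])
  for (j in seq_len(ncol(m))) {
    col <- suppressWarnings(as.numeric(m[, j]))
    bad <- which(is.na(col) | col < 0 | col != round(col))
    if (length(bad)) {
      stop(sprintf(
        "invalid count for OTU '%s', sample '%s': '%s' (must be a non-negative integer)",
        otu_ids[bad[1]], sample_ids[j], m[bad[1], j]), call. = FALSE)
    }
  }
  out <- t(matrix(as.integer(m), nrow = nrow(m),
                  dimnames = list(otu_ids, sample_ids)))
  check_otu_matrix(out)
  out
}

check_otu_matrix <- function(otu) {
  if (!is.matrix(otu) || !is.numeric(otu)) {
    stop("OTU table must be a numeric matrix (samples x OTUs)", call. = FALSE)
  }
  if (is.null(rownames(otu)) || is.null(colnames(otu))) {
    stop("OTU table must have sample and OTU dimnames", call. = FALSE)
  }
  stop_if_duplicates(rownames(otu), "sample ids")
  stop_if_duplicates(colnames(otu), "OTU ids")
  if (anyNA(otu) || any(otu < 0) || any(otu != round(otu))) {
    bad <- which(is.na(otu) | otu < 0 | otu != round(otu), arr.ind = TRUE)[1, ]
    stop(sprintf("invalid count at sample '%s', OTU '%s'",
                 rownames(otu)[bad[1]], colnames(otu)[bad[2]]), call. = FALSE)
  }
  invisible(otu)
}

#' Write / read a taxonomy table
#'
#' Fixed ranks domain, phylum, class, order, family, genus; missing ranks are
#' stored as empty strings and never dropped. The order column drives
#' chloroplast filtering downstream.
#'
#' @param taxonomy data.frame with columns `otu_id`, `domain` .. `genus`.
#' @param path file path.
#' @return `read_taxonomy()` returns the validated data.frame.
#' @export
write_taxonomy <- function(taxonomy, path) {
  check_taxonomy(taxonomy)
  utils::write.table(taxonomy[, c("otu_id", TAX_RANKS)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_taxonomy
#' @export
read_taxonomy <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                          colClasses = "character", fileEncoding = "UTF-8")
  check_taxonomy(df)
  df[, c("otu_id", TAX_RANKS)]
}

check_taxonomy <- function(taxonomy) {
  if (!is.data.frame(taxonomy)) stop("taxonomy must be a data.frame",
                                     call. = FALSE)
  missing_cols <- setdiff(c("otu_id", TAX_RANKS), names(taxonomy))
  if (length(missing_cols)) {
    stop("taxonomy is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stop_if_duplicates(taxonomy$otu_id, "taxonomy OTU ids")
  invisible(taxonomy)
}

#' Write / read sample metadata
#'
#' One row per sample: species, kit, replicate index, control flag and the
#' QC measurements (DNA concentration in ng/uL, input mass in g, DIN,
#' absorbance ratios, PCR dilution factor as `1`/`10`/`100`/`failed`).
#' Concentrations below the 0.1 ng/uL fluorometer detection floor are stored
#' as 0.1 with a warning on read, mirroring how sub-detection measurements
#' are handled upstream.
#'
#' @param metadata data.frame of sample records.
#' @param path file path.
#' @return `read_metadata()` returns the validated data.frame.
#' @export
write_metadata <- function(metadata, path) {
  check_metadata(metadata)
  utils::write.csv(metadata, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(dilution_factor = "character"),
                        fileEncoding = "UTF-8")
  low <- !is.na(df$dna_conc) & df$dna_conc < 0.1
  if (any(low)) {
    warning(sprintf(
      "%d sample(s) below the 0.1 ng/uL detection floor; set to 0.1: %s",
      sum(low), paste(df$sample_id[low], collapse = ", ")), call. = FALSE)
    df$dna_conc[low] <- 0.1
  }
  check_metadata(df)
  df
}

metadata_columns <- c("sample_id", "species", "kit", "replicate",
                      "is_control", "dna_conc", "input_mass", "din",
                      "a260_280", "a260_230", "dilution_factor")

check_metadata <- function(metadata) {
  if (!is.data.frame(metadata)) stop("metadata must be a data.frame",
                                     call. = FALSE)
  missing_cols <- setdiff(metadata_columns, names(metadata))
  if (length(missing_cols)) {
    stop("metadata is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stop_if_duplicates(metadata$sample_id, "sample ids")
  bad <- !metadata$dilution_factor %in% DILUTION_LEVELS
  if (any(bad)) {
    stop(sprintf("invalid dilution_factor for sample '%s': '%s'",
                 metadata$sample_id[which(bad)[1]],
                 metadata$dilution_factor[which(bad)[1]]), call. = FALSE)
  }
  if (any(metadata$replicate < 1)) {
    stop("replicate indices must be >= 1", call. = FALSE)
  }
  ctrl <- metadata$is_control & metadata$species != CONTROL_SPECIES
  if (any(ctrl)) {
    stop(sprintf("control sample '%s' must carry the species label '%s'",
                 metadata$sample_id[which(ctrl)[1]], CONTROL_SPECIES),
         call. = FALSE)
  }
  invisible(metadata)
}

#' Write / read kit profiles
#'
#' Per-kit bench attributes used by the ranking stage: a simplicity score
#' (integer 1 = simplest .. 5) and cost per sample.
#'
#' @param kits data.frame with columns `kit`, `simplicity`,
#'   `cost_per_sample`.
#' @param path file path.
#' @return `read_kit_profiles()` returns the validated data.frame.
#' @export
write_kit_profiles <- function(kits, path) {
  check_kit_profiles(kits)
  utils::write.csv(kits, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_kit_profiles
#' @export
read_kit_profiles <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  check_kit_profiles(df)
  df
}

check_kit_profiles <- function(kits) {
  if (!is.data.frame(kits)) stop("kit profiles must be a data.frame",
                                 call. = FALSE)
  missing_cols <- setdiff(c("kit", "simplicity", "cost_per_sample"),
                          names(kits))
  if (length(missing_cols)) {
    stop("kit profiles missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  stop_if_duplicates(kits$kit, "kit names")
  bad <- !kits$simplicity %in% 1:5
  if (any(bad)) {
    stop(sprintf("kit '%s': simplicity must be an integer in 1..5",
                 kits$kit[which(bad)[1]]), call. = FALSE)
  }
  if (any(kits$cost_per_sample <= 0)) {
    stop("cost_per_sample must be positive", call. = FALSE)
  }
  invisible(kits)
}

#' Cross-validate an OTU table against its companion tables
#'
#' Every sample in the OTU table must have a metadata row and every OTU a
#' taxonomy row; violations are reported by id.
#'
#' @param otu samples x OTUs count matrix.
#' @param taxonomy taxonomy data.frame.
#' @param metadata sample metadata data.frame.
#' @return invisibly `TRUE` on success.
#' @export
validate_dataset <- function(otu, taxonomy, metadata) {
  check_otu_matrix(otu)
  check_taxonomy(taxonomy)
  check_metadata(metadata)
  missing_samples <- setdiff(rownames(otu), metadata$sample_id)
  if (length(missing_samples)) {
    stop("samples missing from metadata: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  missing_otus <- setdiff(colnames(otu), taxonomy$otu_id)
  if (length(missing_otus)) {
    stop("OTUs missing from taxonomy: ",
         paste(missing_otus, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Write a rank report
#'
#' Serialises one or more rank tables (see [aggregate_ranks()]) to JSON,
#' including the per-criterion rank matrices and the Total/Quality orders.
#'
#' @param ranks a `rank_table` or named list of them (one per species).
#' @param path output path.
#' @return invisibly the path.
#' @export
write_rank_report <- function(ranks, path) {
  if (inherits(ranks, "rank_table")) ranks <- list(ranks)
  payload <- lapply(ranks, function(rt) {
    list(species = rt$species,
         per_criterion_ranks = as.data.frame(rt$per_criterion_ranks),
         total = as.list(rt$total), quality = as.list(rt$quality),
         total_position = as.list(rt$total_position),
         quality_position = as.list(rt$quality_position),
         total_rank_order = rt$total_rank_order,
         quality_rank_order = rt$quality_rank_order,
         notes = rt$notes)
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a full synthetic dataset to a directory
#'
#' Emits the OTU table (TSV), taxonomy (TSV), metadata (CSV), kit profiles
#' (CSV) and the ground-truth bundle (JSON) of a [generate_benchmark_dataset()]
#' result.
#'
#' @param dataset a `kitbench_dataset`.
#' @param dir output directory (created if absent).
#' @return invisibly the directory.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "kitbench_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_otu_table(dataset$otu, file.path(dir, "otu_table.tsv"))
  write_taxonomy(dataset$taxonomy, file.path(dir, "taxonomy.tsv"))
  write_metadata(dataset$metadata, file.path(dir, "metadata.csv"))
  write_kit_profiles(dataset$kits, file.path(dir, "kits.csv"))
  jsonlite::write_json(dataset$truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
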