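# File formats and run configuration: SMILES lists, product tables (CSV,
# SDF), audit logs (JSON-lines) and the YAML run configuration.

#' Read a SMILES file
#'
#' One record per line: SMILES, optionally followed by a whitespace-separated
#' identifier.  Missing identifiers are generated.
#'
#' @param path Input file.
#' @return Tibble with columns smiles, bb_id.
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0)
    return(tibble::tibble(smiles = character(0), bb_id = character(0)))
  parts <- strsplit(lines, "[[:space:]]+")
  tibble::tibble(
    smiles = vapply(parts, `[`, character(1), 1),
    bb_id = vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1) parts[[i]][2] else sprintf("BB%04d", i)
    }, character(1))
  )
}

#' Write a SMILES file
#'
#' @param x Data frame whose first column is SMILES and second identifiers.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(x, path) {
  writeLines(paste(x[[1]], x[[2]]), path)
  invisible(path)
}

#' Write the saved-reaction table as CSV
#'
#' @param records Record tibble from [run_library()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_products_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE, na = "")
  invisible(path)
}

#' Write products as an SD file with annotation data fields
#'
#' Data fields are namespaced `SF_` (SF_ID, SF_TRANSFORM, SF_BB_A, SF_BB_B,
#' SF_DELTA, SF_CLASS, plus one field per annotation column when an
#' annotation table is supplied).
#'
#' @param records Record tibble from [run_library()].
#' @param path Output SDF path.
#' @param annotations Optional annotation tibble ([annotate_products()])
#'   aligned with `records` rows.
#' @return Number of molecules written, invisibly.
#' @export
write_products_sdf <- function(records, path, annotations = NULL) {
  recs <- lapply(seq_len(nrow(records)), function(i) {
    props <- list(
      SF_ID = records$product_id[i],
      SF_TRANSFORM = records$transform_id[i],
      SF_BB_A = records$bb_a[i],
      SF_BB_B = records$bb_b[i],
      SF_DELTA = records$delta[i],
      SF_CLASS = records$class_label[i]
    )
    if (!is.null(annotations)) {
      for (cl in setdiff(colnames(annotations), c("smiles", "annotation_error"))) {
        props[[paste0("SF_", toupper(cl))]] <- annotations[[cl]][i]
      }
    }
    list(smiles = records$product_smiles[i], id = records$product_id[i],
         props = props)
  })
  res <- chem_call("write_sdf", list(path = path, records = recs))
  invisible(res$written)
}

#' Write the audit log as JSON-lines
#'
#' @param audit Audit tibble from [run_library()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_audit_jsonl <- function(audit, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (i in seq_len(nrow(audit))) {
    writeLines(as.character(jsonlite::toJSON(as.list(audit[i, ]),
                                             auto_unbox = TRUE, na = "null")), con)
  }
  invisible(path)
}

#' Append a stage log line (JSON-lines)
#'
#' @param stage Stage name.
#' @param counts Named list/vector of counters.
#' @param path Log file (appended).
#' @return `path`, invisibly.
#' @export
stage_log <- function(stage, counts, path) {
  line <- jsonlite::toJSON(c(list(stage = stage), as.list(counts)),
                           auto_unbox = TRUE)
  cat(as.character(line), "\n", sep = "", file = path, append = TRUE)
  invisible(path)
}

#' Run configuration
#'
#' @param rules Path to the rule YAML (default: shipped set).
#' @param bb_path Path to the building-block SMILES file.
#' @param out_dir Output directory.
#' @param complexity_cutoff Bertz complexity cutoff for [filter_bbs()].
#' @param seed Seed for fixture generation.
#' @return Object of class `run_config` (a named list).
#' @export
run_config <- function(rules = NULL, bb_path = NULL, out_dir = ".",
                       complexity_cutoff = 1200, seed = 20201111) {
  structure(list(rules = rules, bb_path = bb_path, out_dir = out_dir,
                 complexity_cutoff = complexity_cutoff, seed = seed),
            class = "run_config")
}

#' Read/write a run configuration (YAML)
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  do.call(run_config, x[intersect(names(x), names(formals(run_config)))])
}

#' @rdname read_run_config
#' @param config A `run_config` to write.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
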