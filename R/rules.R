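# Rule model: the declarative reaction-rule format.
#
# A transform is one reaction chemistry: two reactant role patterns (SMARTS),
# a product template (SMIRKS), the leaving groups the template drops, and an
# ordered list of scoring clauses.  Clauses raise (ADD) or lower (SUBTRACT)
# the reaction score in increments of five, or veto it outright (KILL).

.CLAUSE_SCOPES <- c("reactant_a", "reactant_b", "product")
.CLAUSE_ACTIONS <- c("ADD", "SUBTRACT", "KILL")
.CLAUSE_PROPERTIES <- c("heavy_atoms", "ring_count", "net_charge")
.CLAUSE_OPS <- c("<", "<=", ">", ">=", "==")

.rule_error <- function(id, field, msg) {
  stop(sprintf("rule %s, field '%s': %s", as.character(id), field, msg),
       call. = FALSE)
}

.validate_clause <- function(cl, id, idx, permissive = FALSE) {
  field <- sprintf("clauses[%d]", idx)
  if (is.null(cl$scope) || !cl$scope %in% .CLAUSE_SCOPES)
    .rule_error(id, field, "scope must be one of reactant_a/reactant_b/product")
  if (is.null(cl$action) || !cl$action %in% .CLAUSE_ACTIONS)
    .rule_error(id, field, "action must be ADD, SUBTRACT or KILL")
  has_smarts <- !is.null(cl$smarts)
  has_prop <- !is.null(cl$property)
  if (has_smarts == has_prop)
    .rule_error(id, field, "exactly one of 'smarts' or 'property' is required")
  if (has_prop) {
    if (!cl$property %in% .CLAUSE_PROPERTIES)
      .rule_error(id, field, paste("unknown property; allowed:",
                                   paste(.CLAUSE_PROPERTIES, collapse = ", ")))
    if (is.null(cl$op) || !cl$op %in% .CLAUSE_OPS)
      .rule_error(id, field, "property predicate needs a comparison 'op'")
    if (is.null(cl$threshold) || !is.numeric(cl$threshold))
      .rule_error(id, field, "property predicate needs a numeric 'threshold'")
  }
  if (cl$action == "KILL") {
    if (!is.null(cl$value))
      .rule_error(id, field, "KILL clauses carry no value")
  } else {
    v <- cl$value
    if (is.null(v) || !is.numeric(v))
      .rule_error(id, field, "ADD/SUBTRACT clauses need an integer value")
    v <- as.integer(v)
    if (!permissive && (v %% 5L != 0L || v < 5L || v > 30L))
      .rule_error(id, field, sprintf(
        "value %d is not a positive multiple of 5 in [5, 30]", v))
    cl$value <- v
  }
  cl
}

new_transform <- function(x, permissive = FALSE) {
  for (f in c("id", "name", "ring_forming", "role_a", "role_b",
              "product_smirks")) {
    if (is.null(x[[f]])) .rule_error(.pluck(x, "id", "?"), f, "missing")
  }
  for (role in c("role_a", "role_b")) {
    if (is.null(x[[role]]$smarts)) .rule_error(x$id, role, "missing 'smarts'")
  }
  x$id <- as.integer(x$id)
  x$ring_forming <- isTRUE(x$ring_forming)
  if (is.null(x$leaving_groups)) x$leaving_groups <- list()
  if (is.null(x$clauses)) x$clauses <- list()
  x$clauses <- lapply(seq_along(x$clauses), function(i) {
    .validate_clause(x$clauses[[i]], x$id, i, permissive = permissive)
  })
  if (is.null(x$metadata)) x$metadata <- list()
  structure(x, class = "transform")
}

#' @export
print.transform <- function(x, ...) {
  cat(sprintf("<transform %d: %s%s>\n", x$id, x$name,
              if (x$ring_forming) " [ring-forming]" else ""))
  cat(sprintf("  A: %s   B: %s\n", x$role_a$smarts, x$role_b$smarts))
  cat(sprintf("  %d clause(s), %d leaving group(s)\n",
              length(x$clauses), length(x$leaving_groups)))
  invisible(x)
}

#' Load reaction rules from a YAML file
#'
#' Reads and validates a rule file against the documented schema (shipped as
#' `inst/schema/transforms.schema.json`).  Every SMARTS role pattern, clause
#' pattern and product SMIRKS is parse-checked by the chemistry backend;
#' violations raise an error naming the rule id and field.
#'
#' @param path Path to the YAML rule file.
#' @param permissive If `TRUE`, clause values outside the 5..30
#'   multiple-of-five convention are accepted.
#' @return A list of `transform` objects.
#' @export
load_rules <- function(path, permissive = FALSE) {
  doc <- yaml::read_yaml(path)
  raw <- doc$transforms
  if (is.null(raw)) raw <- list()
  if (length(raw) == 0) return(list())
  transforms <- lapply(raw, new_transform, permissive = permissive)
  ids <- vapply(transforms, function(t) t$id, integer(1))
  if (anyDuplicated(ids))
    stop("duplicate transform id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  # batch pattern validation
  smarts <- unlist(lapply(transforms, function(t) {
    c(t$role_a$smarts, t$role_b$smarts,
      unlist(lapply(t$clauses, function(cl) cl$smarts)))
  }))
  smirks <- vapply(transforms, function(t) t$product_smirks, character(1))
  chk <- chem_call("parse_check", list(smarts = unique(smarts), smirks = smirks))
  bad_smarts <- Filter(function(r) !isTRUE(r$ok), chk$smarts)
  if (length(bad_smarts) > 0)
    stop("unparseable SMARTS pattern: ", bad_smarts[[1]]$pattern, call. = FALSE)
  bad_smirks <- Filter(function(r) !isTRUE(r$ok), chk$smirks)
  if (length(bad_smirks) > 0)
    stop("unparseable SMIRKS template: ", bad_smirks[[1]]$pattern, call. = FALSE)
  transforms
}

#' The rule set shipped with the package
#'
#' Eight two-reactant transforms (amide, sulfonamide, biaryl coupling, ether
#' synthesis, azide-alkyne cycloaddition, aryl amination, pyrrole synthesis,
#' benzimidazole condensation), three of them ring-forming.
#'
#' @inheritParams load_rules
#' @return A list of `transform` objects.
#' @export
default_transforms <- function(permissive = FALSE) {
  load_rules(system.file("rules", "transforms.yaml", package = "synthforge",
                         mustWork = TRUE),
             permissive = permissive)
}

#' Serialize transforms back to YAML
#'
#' Inverse of [load_rules()]: `load_rules(write_rules(x, f))` is semantically
#' identical to `x` (same patterns, clause order, values).
#'
#' @param transforms List of `transform` objects.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_rules <- function(transforms, path) {
  doc <- list(transforms = lapply(transforms, function(t) {
    t <- unclass(t)
    t$id <- as.integer(t$id)
    t
  }))
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' Validate a transform beyond schema checks
#'
#' Returns human-readable diagnostics instead of raising: duplicated clauses,
#' atom bookkeeping mismatches between the product template and the declared
#' leaving groups, and role examples that disagree with the role pattern or
#' the template's reactant sides.
#'
#' @param t A `transform`.
#' @return Character vector of diagnostics; empty when all invariants hold.
#' @export
validate_transform <- function(t) {
  diags <- character(0)
  # duplicate clauses (identical scope/action/value/predicate)
  if (length(t$clauses) > 1) {
    sig <- vapply(t$clauses, function(cl) {
      paste(cl$scope, cl$action, .pluck(cl, "value", ""),
            .pluck(cl, "smarts", ""), .pluck(cl, "property", ""),
            .pluck(cl, "op", ""), .pluck(cl, "threshold", ""), sep = "|")
    }, character(1))
    if (anyDuplicated(sig))
      diags <- c(diags, sprintf("rule %d: duplicated clause(s): %s", t$id,
                                paste(unique(sig[duplicated(sig)]), collapse = "; ")))
  }
  # atom bookkeeping: template-dropped heavy atoms must equal declared leaving atoms
  info <- chem_call("smirks_info", list(smirks = t$product_smirks))$records[[1]]
  if (!isTRUE(info$ok)) {
    diags <- c(diags, sprintf("rule %d: product template does not parse: %s",
                              t$id, .pluck(info, "error", "")))
    return(diags)
  }
  declared <- sum(vapply(t$leaving_groups,
                         function(lg) as.numeric(lg$heavy_atoms), numeric(1)))
  if (length(t$leaving_groups) == 0) declared <- 0
  if (info$dropped_atoms != declared)
    diags <- c(diags, sprintf(
      "rule %d: template drops %d mapped atom(s) but leaving_groups declare %d",
      t$id, info$dropped_atoms, as.integer(declared)))
  if (info$added_atoms > 0 && is.null(t$metadata$allow_added_atoms))
    diags <- c(diags, sprintf(
      "rule %d: product template introduces %d atom(s) from nowhere",
      t$id, info$added_atoms))
  if (info$n_reactant_templates != 2)
    diags <- c(diags, sprintf("rule %d: expected 2 reactant templates, found %d",
                              t$id, info$n_reactant_templates))
  # role examples: must match the role pattern exactly once, and the
  # template's corresponding reactant side must accept them
  examples <- c(.pluck(t$role_a, "example", NA), .pluck(t$role_b, "example", NA))
  if (!anyNA(examples)) {
    sides <- strsplit(t$product_smirks, ">>", fixed = TRUE)[[1]][1]
    templ <- strsplit(sides, ".", fixed = TRUE)[[1]]
    pats <- c(t$role_a$smarts, t$role_b$smarts, templ)
    m <- match_sites(pats, examples)
    for (i in 1:2) {
      role_nm <- c("role_a", "role_b")[i]
      if (is.na(m[i, i]) || m[i, i] != 1L)
        diags <- c(diags, sprintf(
          "rule %d: %s example matches its role pattern %s times (expected 1)",
          t$id, role_nm, m[i, i]))
      if (length(templ) == 2 && (is.na(m[2 + i, i]) || m[2 + i, i] < 1L))
        diags <- c(diags, sprintf(
          "rule %d: %s example is not accepted by the template's reactant side",
          t$id, role_nm))
    }
  }
  diags
}
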