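# Reaction-rule objects and rule-file I/O (YAML or TSV).

rule_file_error <- function(path, record, why) {
  abort_ncm("rule_file_error",
            sprintf("rule file '%s', record %s: %s", path, record, why),
            path = path, record = record)
}

new_rule <- function(rule_id, name, category, reaction_smarts, notes = "") {
  list(rule_id = rule_id, name = name, category = category,
       reaction_smarts = reaction_smarts, notes = notes,
       rxn = parse_reaction_smarts(reaction_smarts))
}

validate_rule_record <- function(rec, path, pos) {
  where <- if (!is.null(rec$rule_id) && nzchar(rec$rule_id %||% "")) {
    sprintf("%d (rule_id '%s')", pos, rec$rule_id)
  } else as.character(pos)
  for (f in c("rule_id", "name", "category", "reaction_smarts")) {
    v <- rec[[f]]
    if (is.null(v) || is.na(v) || !nzchar(trimws(as.character(v)))) {
      rule_file_error(path, where, sprintf("missing field '%s'", f))
    }
  }
  if (!rec$category %in% group_categories()) {
    rule_file_error(path, where,
                    sprintf("category '%s' is not one of the eight labels (%s)",
                            rec$category,
                            paste(group_categories(), collapse = ", ")))
  }
  rule <- tryCatch(
    new_rule(rec$rule_id, rec$name, rec$category, rec$reaction_smarts,
             if (is.null(rec$notes) || is.na(rec$notes)) "" else rec$notes),
    error = function(e) rule_file_error(path, where, conditionMessage(e))
  )
  rule
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_ruleset <- function(rules, source_path = NA_character_) {
  structure(list(rules = rules, source_path = source_path),
            class = "nc_ruleset")
}

#' Load a reaction-rule file
#'
#' Reads a rule file in YAML (a list of records) or TSV (header columns
#' `rule_id`, `name`, `category`, `reaction_smarts`, `notes`) form, compiles
#' every reaction SMARTS and validates the closed category vocabulary and
#' rule-id uniqueness. The first invalid record aborts with a classed
#' `rule_file_error` naming it.
#'
#' @param path Path to a `.yaml`/`.yml` or `.tsv`/`.txt` rule file.
#' @return An `nc_ruleset`.
#' @export
#' @examples
#' rs <- load_ruleset(system.file("extdata", "reaction_rules.yaml",
#'                                package = "ncmetab"))
#' length(rs$rules)
load_ruleset <- function(path) {
  if (!file.exists(path)) {
    rule_file_error(path, "-", "file does not exist")
  }
  ext <- tolower(tools::file_ext(path))
  recs <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else if (ext %in% c("tsv", "txt")) {
    df <- utils::read.delim(path, stringsAsFactors = FALSE,
                            colClasses = "character")
    need <- c("rule_id", "name", "category", "reaction_smarts")
    if (!all(need %in% names(df))) {
      rule_file_error(path, "-",
                      paste("missing column(s):",
                            paste(setdiff(need, names(df)), collapse = ", ")))
    }
    if (!"notes" %in% names(df)) df$notes <- ""
    lapply(seq_len(nrow(df)), function(i) as.list(df[i, ]))
  } else {
    rule_file_error(path, "-", sprintf("unsupported extension '%s'", ext))
  }
  if (!length(recs)) rule_file_error(path, "-", "no rule records")
  rules <- vector("list", length(recs))
  seen <- character()
  for (i in seq_along(recs)) {
    r <- validate_rule_record(recs[[i]], path, i)
    if (r$rule_id %in% seen) {
      rule_file_error(path, sprintf("%d (rule_id '%s')", i, r$rule_id),
                      "duplicate rule_id")
    }
    seen <- c(seen, r$rule_id)
    rules[[i]] <- r
  }
  names(rules) <- seen
  new_ruleset(rules, source_path = normalizePath(path))
}

#' Write a rule set back to YAML or TSV
#'
#' @param ruleset An `nc_ruleset`.
#' @param path Output path; format chosen by extension as in [load_ruleset()].
#' @return `path`, invisibly.
#' @export
write_ruleset <- function(ruleset, path) {
  recs <- lapply(ruleset$rules, function(r) {
    r[c("rule_id", "name", "category", "reaction_smarts", "notes")]
  })
  names(recs) <- NULL
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(recs, path)
  } else {
    df <- do.call(rbind, lapply(recs, as.data.frame))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

ruleset_env <- new.env(parent = emptyenv())

#' The rule set shipped with the package
#'
#' Eighteen enzyme-free transformation rules, at least two per
#' functional-group category, loaded from the bundled
#' `extdata/reaction_rules.yaml`.
#'
#' @return An `nc_ruleset`.
#' @export
default_ruleset <- function() {
  if (is.null(ruleset_env$default)) {
    ruleset_env$default <- load_ruleset(
      system.file("extdata", "reaction_rules.yaml", package = "ncmetab")
    )
  }
  ruleset_env$default
}

as_ruleset <- function(x) {
  if (inherits(x, "nc_ruleset")) return(x)
  if (is.character(x) && length(x) == 1L) return(load_ruleset(x))
  stop("expected an nc_ruleset or a rule-file path")
}

rule_categories <- function(ruleset) {
  vapply(ruleset$rules, function(r) r$category, character(1))
}

#' @export
print.nc_ruleset <- function(x, ...) {
  cats <- table(factor(rule_categories(x), levels = group_categories()))
  cat(sprintf("<ruleset> %d rules (%s)\n", length(x$rules),
              if (is.na(x$source_path)) "in-memory" else x$source_path))
  for (nm in names(cats)) cat(sprintf("  %-10s %d\n", nm, cats[[nm]]))
  invisible(x)
}

ruleset_checksum <- function(ruleset) {
  if (!is.na(ruleset$source_path) && file.exists(ruleset$source_path)) {
    unname(tools::md5sum(ruleset$source_path))
  } else {
    smarts <- vapply(ruleset$rules, function(r) r$reaction_smarts, character(1))
    tmp <- tempfile()
    on.exit(unlink(tmp))
    writeLines(smarts, tmp)
    unname(tools::md5sum(tmp))
  }
}
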