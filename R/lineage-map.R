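#' @importFrom rlang .data %||% abort warn
#' @importFrom tibble tibble as_tibble
#' @import dplyr
NULL

VALID_DOMAINS <- c("Archaea", "Eukarya", "Bacteria", "Unknown")

#' Construct a lineage map
#'
#' A lineage map binds verbatim leaf labels to a three-level taxonomic
#' classification (`domain`, `group`, `lineage`) used by every topological
#' query in the package. Exact-label records take precedence over ordered
#' prefix rules, so curation-level fixes (e.g. a Hodarchaeales genome still
#' annotated as *Heimdallarchaeaceae*) are made in the map, never in code.
#'
#' @param records A data frame with columns `label`, `domain`, `group`,
#'   `lineage`; one row per exactly-matched leaf label.
#' @param rules A data frame with columns `pattern`, `domain`, `group`,
#'   `lineage`; a label matches a rule when it starts with `pattern`.
#'   Rules are tried in order and the first match wins.
#' @return An object of class `lineage_map`.
#' @examples
#' m <- lineage_map(
#'   records = tibble::tibble(label = "E_hs", domain = "Eukarya",
#'                            group = "Eukarya", lineage = "Eukarya"),
#'   rules = tibble::tibble(pattern = "Hod_", domain = "Archaea",
#'                          group = "Asgard", lineage = "Hodarchaeales"))
#' classify_taxa(c("E_hs", "Hod_gx01", "mystery"), m)
#' @export
lineage_map <- function(records = NULL, rules = NULL) {
  empty <- tibble(label = character(), domain = character(),
                  group = character(), lineage = character())
  if (is.null(records)) records <- empty
  records <- as_tibble(records)[, c("label", "domain", "group", "lineage")]
  if (is.null(rules)) {
    rules <- tibble(pattern = character(), domain = character(),
                    group = character(), lineage = character())
  }
  rules <- as_tibble(rules)[, c("pattern", "domain", "group", "lineage")]
  validate_map_rows(records, rules)
  structure(list(records = records, rules = rules), class = "lineage_map")
}

validate_map_rows <- function(records, rules) {
  dup <- records$label[duplicated(records$label)]
  if (length(dup) > 0) {
    abort(paste0("duplicate label(s) in lineage map: ",
                 paste(unique(dup), collapse = ", ")))
  }
  bad <- setdiff(unique(c(records$domain, rules$domain)), VALID_DOMAINS)
  if (length(bad) > 0) {
    abort(paste0("invalid domain(s): ", paste(bad, collapse = ", "),
                 " (expected ", paste(VALID_DOMAINS, collapse = "/"), ")"))
  }
  if (any(!nzchar(records$label))) abort("empty label in lineage map")
  euk <- records$domain == "Eukarya" & records$group != "Eukarya"
  if (any(euk)) abort("records with domain Eukarya must have group Eukarya")
  invisible(TRUE)
}

#' Read a lineage map from a TSV file
#'
#' The file is tab-delimited with a header line `label` (or `pattern`),
#' `domain`, `group`, `lineage`. Lines starting with `#` are comments.
#' Rows whose first field ends in `*` are prefix rules (the `*` is
#' stripped and the remainder matched as a label prefix, in file order);
#' all other rows are exact-label records. Exact records outrank rules.
#'
#' @param path Path to the TSV file.
#' @return A [lineage_map()].
#' @export
read_lineage_map <- function(path) {
  if (!file.exists(path)) abort(paste0("lineage map not found: ", path))
  lines <- readr::read_lines(path)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) abort(paste0("lineage map is empty: ", path))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  bad <- which(nf != 4)
  if (length(bad) > 0) {
    abort(sprintf("malformed lineage-map row at line %d of %s (%d fields, expected 4)",
                  keep[bad[1]], path, nf[bad[1]]))
  }
  m <- do.call(rbind, fields)
  header <- tolower(trimws(m[1, ]))
  if (!header[1] %in% c("label", "pattern") ||
      !identical(header[2:4], c("domain", "group", "lineage"))) {
    abort(paste0("lineage map header must be label|pattern, domain, group, lineage; got: ",
                 paste(m[1, ], collapse = ", ")))
  }
  m <- m[-1, , drop = FALSE]
  if (nrow(m) == 0) abort(paste0("lineage map has a header but no rows: ", path))
  first <- trimws(m[, 1])
  is_rule <- endsWith(first, "*")
  records <- tibble(label = first[!is_rule], domain = trimws(m[!is_rule, 2]),
                    group = trimws(m[!is_rule, 3]), lineage = trimws(m[!is_rule, 4]))
  rules <- tibble(pattern = sub("\\*$", "", first[is_rule]),
                  domain = trimws(m[is_rule, 2]),
                  group = trimws(m[is_rule, 3]), lineage = trimws(m[is_rule, 4]))
  lineage_map(records, rules)
}

#' Classify leaf labels against a lineage map
#'
#' Lookup is deterministic: an exact record wins over any rule; otherwise
#' the first matching prefix rule wins; unmatched labels are returned with
#' `domain = "Unknown"` rather than raising an error, so surveys tolerate
#' stray leaves.
#'
#' @param labels Character vector of leaf labels.
#' @param map A [lineage_map()].
#' @return A tibble with one row per label: `label`, `domain`, `group`,
#'   `lineage`, and `matched` (`"exact"`, `"prefix"`, or `"none"`).
#' @export
classify_taxa <- function(labels, map) {
  stopifnot(inherits(map, "lineage_map"))
  labels <- as.character(labels)
  n <- length(labels)
  domain <- rep("Unknown", n); group <- rep("Unknown", n)
  lineage <- rep("Unknown", n); matched <- rep("none", n)
  hit <- match(labels, map$records$label)
  ex <- !is.na(hit)
  if (any(ex)) {
    domain[ex] <- map$records$domain[hit[ex]]
    group[ex] <- map$records$group[hit[ex]]
    lineage[ex] <- map$records$lineage[hit[ex]]
    matched[ex] <- "exact"
  }
  open <- !ex
  for (j in seq_len(nrow(map$rules))) {  # rule order decides ties
    if (!any(open)) break
    m <- open & startsWith(labels, map$rules$pattern[j])
    if (any(m)) {
      domain[m] <- map$rules$domain[j]
      group[m] <- map$rules$group[j]
      lineage[m] <- map$rules$lineage[j]
      matched[m] <- "prefix"
      open <- open & !m
    }
  }
  tibble(label = labels, domain = domain, group = group,
         lineage = lineage, matched = matched)
}

#' @export
print.lineage_map <- function(x, ...) {
  cat(sprintf("<lineage_map: %d exact record(s), %d prefix rule(s)>\n",
              nrow(x$records), nrow(x$rules)))
  if (nrow(x$records) > 0) {
    tab <- dplyr::count(x$records, .data$domain, .data$group)
    print(tab, n = 20)
  }
  invisible(x)
}

#' Write a lineage map to TSV
#'
#' Inverse of [read_lineage_map()]: exact records first, then prefix rules
#' with a trailing `*` on the pattern.
#'
#' @param map A [lineage_map()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lineage_map <- function(map, path) {
  stopifnot(inherits(map, "lineage_map"))
  rec <- map$records
  rul <- map$rules
  body <- c(
    paste("label", "domain", "group", "lineage", sep = "\t"),
    if (nrow(rec) > 0) paste(rec$label, rec$domain, rec$group, rec$lineage, sep = "\t"),
    if (nrow(rul) > 0) paste(paste0(rul$pattern, "*"), rul$domain, rul$group,
                             rul$lineage, sep = "\t"))
  readr::write_lines(body, path)
  invisible(path)
}
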