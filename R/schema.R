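#' Build a questionnaire schema
#'
#' A schema declares every instrument in a survey battery: which trait it
#' measures, its item identifiers, which items are reverse-keyed, the response
#' scale, and how item scores aggregate to a trait score.  Optional subdomain
#' labels partition a subset of an instrument's items (e.g. the aesthetic
#' sensitivity / ease of excitation / low sensory threshold components of the
#' Highly Sensitive Person Scale).
#'
#' @param instruments list of instrument definitions, see [instrument()].
#' @return An object of class `questionnaire_schema`.
#' @seealso [instrument()], [read_schema()], [schema_items()]
#' @export
#' @examples
#' sch <- questionnaire_schema(list(
#'   instrument("hsps", trait = "sps", n_items = 4, scale = c(1, 7)),
#'   instrument("bai", trait = "anxiety", n_items = 3, scale = c(0, 3))
#' ))
#' schema_items(sch)
questionnaire_schema <- function(instruments) {
  if (!is.list(instruments) || length(instruments) == 0L)
    stop_ts("`instruments` must be a non-empty list")
  instruments <- lapply(instruments, validate_instrument)
  ids <- unlist(lapply(instruments, function(i) i$items$id))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_ts("item ids must be globally unique; duplicated: %s",
            paste(dup, collapse = ", "))
  names(instruments) <- vapply(instruments, `[[`, "", "name")
  structure(list(instruments = instruments), class = "questionnaire_schema")
}

#' Define one instrument of a questionnaire schema
#'
#' @param name instrument name (e.g. `"hsps"`).
#' @param trait trait label the instrument measures.
#' @param n_items number of items; ids are generated as `name_q1 ...` unless
#'   `items` is supplied.
#' @param scale integer response range after keying, `c(min, max)`.
#' @param items optional data frame with columns `id`, and optionally
#'   `subdomain` (NA = uncategorized) and `reverse` (logical).
#' @param scoring `"sum"` or `"mean"` aggregation of keyed item scores.
#' @param alt_scoring `"none"` or `"binary"`; binary marks instruments (such
#'   as the Autism Spectrum Quotient) whose graded responses can
#'   alternatively be collapsed to 0/1.
#' @return A validated instrument definition (list).
#' @export
instrument <- function(name, trait, n_items = NULL, scale, items = NULL,
                       scoring = c("sum", "mean"),
                       alt_scoring = c("none", "binary")) {
  scoring <- match.arg(scoring)
  alt_scoring <- match.arg(alt_scoring)
  if (is.null(items)) {
    if (is.null(n_items)) stop_ts("give either `n_items` or `items`")
    items <- data.frame(id = sprintf("%s_q%d", name, seq_len(n_items)),
                        subdomain = NA_character_, reverse = FALSE,
                        stringsAsFactors = FALSE)
  }
  validate_instrument(list(name = name, trait = trait, items = items,
                           scale = as.numeric(scale), scoring = scoring,
                           alt_scoring = alt_scoring))
}

validate_instrument <- function(ins) {
  for (f in c("name", "trait", "items", "scale", "scoring"))
    if (is.null(ins[[f]])) stop_ts("instrument is missing field `%s`", f)
  ins$alt_scoring <- ins$alt_scoring %||% "none"
  items <- as.data.frame(ins$items, stringsAsFactors = FALSE)
  if (is.null(items$id)) stop_ts("instrument `%s`: items need an `id` column", ins$name)
  items$id <- as.character(items$id)
  if (anyDuplicated(items$id))
    stop_ts("instrument `%s`: duplicated item ids", ins$name)
  if (is.null(items$subdomain)) items$subdomain <- NA_character_
  items$subdomain <- as.character(items$subdomain)
  items$subdomain[!is.na(items$subdomain) & items$subdomain == ""] <- NA_character_
  if (is.null(items$reverse)) items$reverse <- FALSE
  items$reverse <- as.logical(items$reverse)
  if (anyNA(items$reverse))
    stop_ts("instrument `%s`: `reverse` must be TRUE/FALSE", ins$name)
  ins$items <- items
  sc <- as.numeric(ins$scale)
  if (length(sc) != 2L || !all(is.finite(sc)) || sc[1] >= sc[2])
    stop_ts("instrument `%s`: scale must be c(min, max) with min < max", ins$name)
  ins$scale <- sc
  if (!ins$scoring %in% c("sum", "mean"))
    stop_ts("instrument `%s`: scoring must be 'sum' or 'mean'", ins$name)
  if (!ins$alt_scoring %in% c("none", "binary"))
    stop_ts("instrument `%s`: alt_scoring must be 'none' or 'binary'", ins$name)
  ins
}

#' Flatten a schema to one row per item
#'
#' @param schema a [questionnaire_schema()].
#' @return data frame with columns `id`, `instrument`, `trait`, `subdomain`,
#'   `reverse`, `scale_min`, `scale_max`.
#' @export
schema_items <- function(schema) {
  stopifnot(inherits(schema, "questionnaire_schema"))
  do.call(rbind, lapply(schema$instruments, function(ins) {
    data.frame(id = ins$items$id, instrument = ins$name, trait = ins$trait,
               subdomain = ins$items$subdomain, reverse = ins$items$reverse,
               scale_min = ins$scale[1], scale_max = ins$scale[2],
               row.names = NULL, stringsAsFactors = FALSE)
  }))
}

#' Read / write questionnaire schemas
#'
#' Schemas are stored as YAML (`.yaml`/`.yml`) or JSON (`.json`).
#'
#' @param path file path; the extension selects the format.
#' @return `read_schema()` returns a `questionnaire_schema`;
#'   `write_schema()` returns `path` invisibly.
#' @export
read_schema <- function(path) {
  if (!file.exists(path)) stop_ts("schema file not found: %s", path)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = FALSE)
  else yaml::read_yaml(path)
  ins <- lapply(raw$instruments, function(i) {
    if (!is.null(i$items) && !is.data.frame(i$items))
      i$items <- do.call(rbind, lapply(i$items, function(it)
        data.frame(id = it$id,
                   subdomain = it$subdomain %||% NA_character_,
                   reverse = isTRUE(it$reverse), stringsAsFactors = FALSE)))
    i$scale <- unlist(i$scale)
    i
  })
  questionnaire_schema(ins)
}

#' @rdname read_schema
#' @param schema a `questionnaire_schema` to serialize.
#' @export
write_schema <- function(schema, path) {
  stopifnot(inherits(schema, "questionnaire_schema"))
  ser <- list(instruments = lapply(unname(schema$instruments), function(i) {
    list(name = i$name, trait = i$trait, scale = as.list(i$scale),
         scoring = i$scoring, alt_scoring = i$alt_scoring,
         items = lapply(seq_len(nrow(i$items)), function(r) {
           it <- i$items[r, ]
           out <- list(id = it$id, reverse = it$reverse)
           if (!is.na(it$subdomain)) out$subdomain <- it$subdomain
           out
         }))
  }))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  else yaml::write_yaml(ser, path)
  invisible(path)
}

#' Restrict a schema to a subset of items
#'
#' Used by the refinement stage to emit modified scale variants (e.g. a
#' 16-item scale after pruning) in the standard schema format.
#'
#' @param schema a `questionnaire_schema`.
#' @param keep character vector of item ids to retain.
#' @return A `questionnaire_schema` containing only the kept items;
#'   instruments left with no items are dropped.
#' @export
subset_schema <- function(schema, keep) {
  stopifnot(inherits(schema, "questionnaire_schema"))
  ins <- lapply(schema$instruments, function(i) {
    i$items <- i$items[i$items$id %in% keep, , drop = FALSE]
    i
  })
  ins <- Filter(function(i) nrow(i$items) > 0L, ins)
  if (!length(ins)) stop_ts("no items left after subsetting")
  questionnaire_schema(unname(ins))
}

#' @export
print.questionnaire_schema <- function(x, ...) {
  it <- schema_items(x)
  cat(sprintf("<questionnaire_schema> %d instruments, %d items\n",
              length(x$instruments), nrow(it)))
  for (ins in x$instruments) {
    sub <- ins$items$subdomain
    nsub <- length(unique(sub[!is.na(sub)]))
    cat(sprintf("  %-14s trait=%-16s %3d items, scale %g-%g%s\n", ins$name,
                ins$trait, nrow(ins$items), ins$scale[1], ins$scale[2],
                if (nsub) sprintf(", %d subdomains", nsub) else ""))
  }
  invisible(x)
}
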