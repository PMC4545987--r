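#' Define a single questionnaire item
#'
#' An item is the atomic unit of an instrument: an identifier, the domain
#' (subscale) it belongs to, the number of ordered response categories, the
#' rating-scale group whose step thresholds it shares, and whether the printed
#' wording runs in the opposite direction to the construct (reverse-scored).
#'
#' Categories are coded `0 .. n_categories - 1` internally; after any reversal
#' higher codes uniformly indicate worse status.
#'
#' @param id unique item identifier (character scalar).
#' @param domain domain / subscale name.
#' @param n_categories number of ordered response categories (>= 2).
#' @param scale_group label of the rating-scale group; items sharing a label
#'   share one set of step thresholds (rating scale model). An item alone in
#'   its group is the partial-credit case.
#' @param reversed logical; `TRUE` if the source coding must be flipped at
#'   read time.
#' @param excluded logical; `TRUE` if the item is scored classically but kept
#'   out of the Rasch calibration.
#' @return a one-row `data.frame` suitable for [instrument_spec()].
#' @export
item_spec <- function(id, domain, n_categories, scale_group = id,
                      reversed = FALSE, excluded = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  n_categories <- as.integer(n_categories)
  if (is.na(n_categories) || n_categories < 2L)
    stop("n_categories must be an integer >= 2 for item '", id, "'")
  data.frame(id = id, domain = domain, n_categories = n_categories,
             scale_group = scale_group, reversed = isTRUE(reversed),
             excluded = isTRUE(excluded), stringsAsFactors = FALSE)
}

#' Assemble an instrument specification
#'
#' Binds item definitions into a validated instrument: item identifiers must
#' be unique, every item belongs to exactly one domain, and all items sharing
#' a rating-scale group must have the same number of categories.
#'
#' @param items a `data.frame` of item rows (see [item_spec()]), or a list of
#'   such rows.
#' @param max_categories upper bound on `n_categories` (default 5, the widest
#'   option set on SGRQ-like instruments).
#' @return an object of class `instrument_spec`: the item table plus domain
#'   bookkeeping.
#' @export
instrument_spec <- function(items, max_categories = 5L) {
  if (is.list(items) && !is.data.frame(items))
    items <- do.call(rbind, items)
  stopifnot(is.data.frame(items))
  required <- c("id", "domain", "n_categories", "scale_group")
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols))
    stop("items table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (is.null(items$reversed)) items$reversed <- FALSE
  if (is.null(items$excluded)) items$excluded <- FALSE
  items$n_categories <- as.integer(items$n_categories)

  if (anyDuplicated(items$id))
    stop("duplicate item id(s): ",
         paste(unique(items$id[duplicated(items$id)]), collapse = ", "))
  if (any(items$n_categories < 2L))
    stop("every item needs at least 2 categories")
  if (any(items$n_categories > max_categories))
    stop("n_categories exceeds max_categories (", max_categories, ") for: ",
         paste(items$id[items$n_categories > max_categories], collapse = ", "))
  for (g in unique(items$scale_group)) {
    m <- unique(items$n_categories[items$scale_group == g])
    if (length(m) > 1L)
      stop("scale group '", g, "' mixes category counts: ",
           paste(m, collapse = ", "))
  }
  rownames(items) <- items$id
  structure(list(items = items,
                 domains = split(items$id, items$domain)),
            class = "instrument_spec")
}

#' @export
print.instrument_spec <- function(x, ...) {
  it <- x$items
  cat("<instrument_spec> ", nrow(it), " items, ",
      length(x$domains), " domain(s)\n", sep = "")
  for (d in names(x$domains)) {
    ids <- x$domains[[d]]
    sub <- it[ids, ]
    cat("  ", d, ": ", length(ids), " items (",
        sum(sub$n_categories == 2L), " dichotomous, ",
        sum(sub$n_categories > 2L), " polytomous)\n", sep = "")
  }
  invisible(x)
}

#' @export
format.instrument_spec <- function(x, ...) {
  paste0("<instrument_spec> ", nrow(x$items), " items")
}

# items of one domain, optionally dropping calibration-excluded ones
spec_items <- function(spec, domain = NULL, analyzed_only = FALSE) {
  it <- spec$items
  if (!is.null(domain)) it <- it[it$domain %in% domain, , drop = FALSE]
  if (analyzed_only) it <- it[!it$excluded, , drop = FALSE]
  it
}

#' Restrict an instrument to one domain
#'
#' @param spec an [instrument_spec()].
#' @param domain domain name(s) to keep.
#' @param analyzed_only drop items flagged `excluded`.
#' @return an `instrument_spec` over the kept items.
#' @export
subset_spec <- function(spec, domain, analyzed_only = TRUE) {
  it <- spec_items(spec, domain, analyzed_only)
  if (!nrow(it)) stop("no items in domain(s): ", paste(domain, collapse = ", "))
  instrument_spec(it)
}

#' Read / write instrument specifications as YAML
#'
#' The on-disk form is a nested key-value file: one entry per item with
#' `domain`, `n_categories`, `scale_group`, and optional `reversed`,
#' `excluded` fields.
#'
#' @param path file path.
#' @return `read_instrument` returns an `instrument_spec`;
#'   `write_instrument` returns `path` invisibly.
#' @export
read_instrument <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$items)) stop("instrument file has no 'items' entry: ", path)
  rows <- lapply(names(raw$items), function(id) {
    e <- raw$items[[id]]
    item_spec(id, domain = e$domain, n_categories = e$n_categories,
              scale_group = if (is.null(e$scale_group)) id else e$scale_group,
              reversed = isTRUE(e$reversed), excluded = isTRUE(e$excluded))
  })
  instrument_spec(rows)
}

#' @rdname read_instrument
#' @param spec an [instrument_spec()] to serialise.
#' @export
write_instrument <- function(spec, path) {
  it <- spec$items
  entries <- lapply(seq_len(nrow(it)), function(i) {
    e <- list(domain = it$domain[i], n_categories = it$n_categories[i],
              scale_group = it$scale_group[i])
    if (it$reversed[i]) e$reversed <- TRUE
    if (it$excluded[i]) e$excluded <- TRUE
    e
  })
  names(entries) <- it$id
  yaml::write_yaml(list(items = entries), path)
  invisible(path)
}
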