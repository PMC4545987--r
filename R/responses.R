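#' Construct a response matrix
#'
#' Persons x items integer category codes with an explicit missing mask (`NA`)
#' and optional per-person covariates. Codes are 0-based: a valid response to
#' an item with `m` categories lies in `0 .. m - 1`. Missingness is preserved,
#' never imputed; the likelihood machinery sums over observed cells only.
#'
#' @param responses integer matrix (persons in rows, items in columns; column
#'   names must match item ids in `spec`).
#' @param spec an [instrument_spec()] used to validate category ranges.
#' @param covariates optional `data.frame` with one row per person (e.g.
#'   `age_years`, `stage`).
#' @param reversal_applied character vector of item ids already recoded from
#'   reversed source wording (provenance, used when writing back).
#' @return object of class `response_matrix`.
#' @export
response_matrix <- function(responses, spec, covariates = NULL,
                            reversal_applied = character()) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  if (is.null(colnames(responses)))
    stop("responses must have item ids as column names")
  unknown <- setdiff(colnames(responses), spec$items$id)
  if (length(unknown))
    stop("unknown item column(s): ", paste(unknown, collapse = ", "))
  if (is.null(rownames(responses)))
    rownames(responses) <- paste0("P", seq_len(nrow(responses)))
  for (j in seq_len(ncol(responses))) {
    id <- colnames(responses)[j]
    m <- spec$items[id, "n_categories"]
    x <- responses[, j]
    bad <- which(!is.na(x) & (x < 0L | x > m - 1L))
    if (length(bad))
      stop("response out of range for item '", id, "', person '",
           rownames(responses)[bad[1]], "': value ", x[bad[1]],
           " not in 0..", m - 1L)
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != nrow(responses))
      stop("covariates must have one row per person")
    rownames(covariates) <- rownames(responses)
  }
  structure(list(responses = responses, covariates = covariates,
                 reversal_applied = reversal_applied),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  r <- x$responses
  cat("<response_matrix> ", nrow(r), " persons x ", ncol(r), " items; ",
      sum(is.na(r)), " missing cell(s)\n", sep = "")
  if (!is.null(x$covariates))
    cat("  covariates: ", paste(names(x$covariates), collapse = ", "), "\n",
        sep = "")
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Read questionnaire responses from a wide CSV
#'
#' Expects one header row of item ids; an optional person-id column and
#' covariate columns are pulled out by name. Cells are integers or empty
#' (missing). Reversed items are recoded at read time as
#' `(n_categories - 1) - x` so that, after recoding, higher codes uniformly
#' indicate worse status; a declared origin offset accommodates 1-based source
#' coding.
#'
#' @param path CSV file path.
#' @param spec an [instrument_spec()].
#' @param person_col name of the person-id column, if present.
#' @param covariate_cols columns to treat as person covariates.
#' @param origin integer offset of the source coding (0 for already 0-based,
#'   1 for 1-based).
#' @return a [response_matrix()].
#' @export
read_responses <- function(path, spec, person_col = "person",
                           covariate_cols = c("age_years", "stage"),
                           origin = 0L) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  covariate_cols <- intersect(covariate_cols, names(df))
  item_cols <- setdiff(names(df), c(person_col, covariate_cols))
  unknown <- setdiff(item_cols, spec$items$id)
  if (length(unknown))
    stop("unknown item column(s) in ", path, ": ",
         paste(unknown, collapse = ", "))
  resp <- as.matrix(df[, item_cols, drop = FALSE])
  storage.mode(resp) <- "integer"
  resp <- resp - as.integer(origin)
  persons <- if (person_col %in% names(df)) as.character(df[[person_col]])
             else paste0("P", seq_len(nrow(resp)))
  rownames(resp) <- persons
  reversed_ids <- intersect(item_cols, spec$items$id[spec$items$reversed])
  for (id in reversed_ids) {
    m <- spec$items[id, "n_categories"]
    # bound-check against the source orientation before flipping
    x <- resp[, id]
    bad <- which(!is.na(x) & (x < 0L | x > m - 1L))
    if (length(bad))
      stop("response out of range for item '", id, "', person '",
           persons[bad[1]], "': value ", x[bad[1]], " not in 0..", m - 1L)
    resp[, id] <- (m - 1L) - x
  }
  covs <- if (length(covariate_cols))
    df[, covariate_cols, drop = FALSE] else NULL
  response_matrix(resp, spec, covariates = covs,
                  reversal_applied = reversed_ids)
}

#' Write responses back to CSV in source orientation
#'
#' Inverse of [read_responses()]: reversed items are flipped back and the
#' origin offset re-applied, so a write/read round trip reproduces the stored
#' cells and missing mask exactly.
#'
#' @param matrix a [response_matrix()].
#' @param spec the matching [instrument_spec()].
#' @param path output CSV path.
#' @param origin integer offset used when the file was read.
#' @export
write_responses <- function(matrix, spec, path, origin = 0L) {
  resp <- matrix$responses
  for (id in intersect(colnames(resp), matrix$reversal_applied)) {
    m <- spec$items[id, "n_categories"]
    resp[, id] <- (m - 1L) - resp[, id]
  }
  resp <- resp + as.integer(origin)
  df <- data.frame(person = rownames(resp), check.names = FALSE)
  if (!is.null(matrix$covariates)) df <- cbind(df, matrix$covariates)
  df <- cbind(df, as.data.frame(resp, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Classical domain scores as percent of maximum
#'
#' Item scores within each domain are summed and expressed as a percentage of
#' the maximum attainable on the items the person actually answered:
#' `100 * sum(x) / sum(m - 1)` over observed items. Higher scores indicate
#' worse status. A person with no observed response in a domain gets `NA`,
#' not zero.
#'
#' @param matrix a [response_matrix()].
#' @param spec an [instrument_spec()].
#' @return `data.frame`, one row per person, one column per domain plus a
#'   `total` column over all items.
#' @export
domain_scores <- function(matrix, spec) {
  resp <- matrix$responses
  out <- data.frame(row.names = rownames(resp))
  score_over <- function(ids) {
    ids <- intersect(ids, colnames(resp))
    if (!length(ids)) return(rep(NA_real_, nrow(resp)))
    sub <- resp[, ids, drop = FALSE]
    maxv <- spec$items[ids, "n_categories"] - 1L
    obs <- !is.na(sub)
    denom <- as.numeric(obs %*% maxv)
    num <- rowSums(sub, na.rm = TRUE)
    unname(ifelse(denom > 0, 100 * num / denom, NA_real_))
  }
  for (d in names(spec$domains)) out[[d]] <- score_over(spec$domains[[d]])
  out$total <- score_over(spec$items$id)
  out
}

#' Collapse response categories
#'
#' Applies an old-category to new-category mapping per item (e.g. merging two
#' rarely distinguished frequency options), returning the recoded matrix and a
#' revised instrument. The mapping must be weakly order-preserving and
#' surjective onto a contiguous range starting at 0. Rating-scale groups are
#' re-derived afterwards so that grouped items still share category counts:
#' items whose new count differs from their group mates move to a derived
#' group label `<group>.<m>`.
#'
#' @param matrix a [response_matrix()].
#' @param spec an [instrument_spec()].
#' @param mapping named list: item id -> integer vector of new categories,
#'   indexed by old category (position 1 = old category 0).
#' @return list with elements `matrix` (recoded [response_matrix()]) and
#'   `spec` (revised [instrument_spec()]).
#' @export
recode_categories <- function(matrix, spec, mapping) {
  unknown <- setdiff(names(mapping), spec$items$id)
  if (length(unknown))
    stop("mapping refers to unknown item(s): ", paste(unknown, collapse = ", "))
  it <- spec$items
  resp <- matrix$responses
  for (id in names(mapping)) {
    map <- as.integer(mapping[[id]])
    m_old <- it[id, "n_categories"]
    if (length(map) != m_old)
      stop("mapping for '", id, "' must cover all ", m_old, " old categories")
    new_vals <- sort(unique(map))
    if (!identical(new_vals, seq(0L, max(map))))
      stop("mapping for '", id,
           "' is not surjective onto a contiguous range starting at 0")
    if (any(diff(map) < 0L))
      stop("mapping for '", id, "' violates order preservation")
    if (id %in% colnames(resp)) {
      x <- resp[, id]
      resp[, id] <- ifelse(is.na(x), NA_integer_, map[x + 1L])
    }
    it[id, "n_categories"] <- max(map) + 1L
  }
  # re-derive scale groups: split groups whose members now disagree on m
  for (g in unique(it$scale_group)) {
    rows <- which(it$scale_group == g)
    ms <- it$n_categories[rows]
    if (length(unique(ms)) > 1L)
      it$scale_group[rows] <- paste0(g, ".", ms)
  }
  new_spec <- instrument_spec(it)
  new_matrix <- response_matrix(resp, new_spec,
                                covariates = matrix$covariates,
                                reversal_applied = matrix$reversal_applied)
  list(matrix = new_matrix, spec = new_spec)
}
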