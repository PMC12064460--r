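# Reserved covariate column names recognized in response CSV files.
.covariate_cols <- c("person_id", "sex", "age_group", "sample_type",
                     "language", "true_theta", "group")

#' Construct a calibrated item bank
#'
#' An item bank is an ordered set of graded-response-model items, each with a
#' discrimination parameter `a` (logistic metric, scaling constant D = 1) and
#' four ordered category thresholds `b1..b4` for five response categories
#' coded 0 ("never") to 4 ("almost always").
#'
#' @param items data frame with columns `item_id`, `a`, `b1`, `b2`, `b3`, `b4`.
#' @param name label for the bank (e.g. `"anxiety"`).
#' @param n_categories number of ordered response categories (fixed at 5).
#' @return An object of class `item_bank`: a list with elements `name`,
#'   `items` (validated data frame) and `n_categories`.
#' @examples
#' bank <- item_bank(data.frame(item_id = "x1", a = 2, b1 = -1, b2 = 0,
#'                              b3 = 0.5, b4 = 1.2))
#' @export
item_bank <- function(items, name = "bank", n_categories = 5L) {
  required <- c("item_id", "a", paste0("b", seq_len(n_categories - 1L)))
  missing_cols <- setdiff(required, names(items))
  if (length(missing_cols) > 0L) {
    stop("item table is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  items <- as.data.frame(items)[required]
  items$item_id <- as.character(items$item_id)
  if (anyDuplicated(items$item_id)) {
    stop("duplicated item_id(s): ",
         paste(unique(items$item_id[duplicated(items$item_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(items$a)) || any(items$a <= 0)) {
    bad <- items$item_id[!is.finite(items$a) | items$a <= 0]
    stop("non-positive discrimination for item(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  b <- bank_thresholds_df(items)
  ok <- apply(b, 1L, function(r) all(is.finite(r)) && !is.unsorted(r))
  if (!all(ok)) {
    stop("thresholds not in non-decreasing order for item(s): ",
         paste(items$item_id[!ok], collapse = ", "), call. = FALSE)
  }
  structure(list(name = name, items = items,
                 n_categories = as.integer(n_categories)),
            class = "item_bank")
}

bank_thresholds_df <- function(items) {
  as.matrix(items[grep("^b[0-9]+$", names(items))])
}

#' @export
print.item_bank <- function(x, ...) {
  cat(sprintf("<item_bank> '%s': %d items, %d categories\n",
              x$name, nrow(x$items), x$n_categories))
  print(x$items, row.names = FALSE)
  invisible(x)
}

#' Number of items in a bank
#' @param bank an `item_bank`.
#' @return integer item count.
#' @export
n_items <- function(bank) nrow(bank$items)

#' Item ids of a bank
#' @param bank an `item_bank`.
#' @return character vector of item ids in bank order.
#' @export
item_ids <- function(bank) bank$items$item_id

#' Discrimination and threshold accessors
#'
#' `bank_a()` returns the vector of discriminations; `bank_b()` the matrix of
#' thresholds (items in rows, b1..b4 in columns), both named by item id.
#'
#' @param bank an `item_bank`.
#' @return numeric vector / matrix.
#' @export
bank_a <- function(bank) {
  stats::setNames(bank$items$a, bank$items$item_id)
}

#' @rdname bank_a
#' @export
bank_b <- function(bank) {
  b <- bank_thresholds_df(bank$items)
  rownames(b) <- bank$items$item_id
  b
}

#' Load an item bank from a file or bundled fixture
#'
#' Reads a CSV or JSON item-parameter table (columns `item_id, a, b1..b4`)
#' and validates it. Two fixtures calibrated on a combined Swedish school and
#' child-and-adolescent-psychiatry sample are bundled: `"anxiety_sv"` (15
#' items) and `"depressive_sv"` (14 items).
#'
#' @param path_or_fixture_name path to a `.csv`/`.json` file, or one of
#'   `"anxiety_sv"`, `"depressive_sv"`.
#' @return validated `item_bank`.
#' @examples
#' anx <- load_item_bank("anxiety_sv")
#' n_items(anx)  # 15
#' @export
load_item_bank <- function(path_or_fixture_name) {
  fixtures <- c(anxiety_sv = "anxiety", depressive_sv = "depressive")
  if (path_or_fixture_name %in% names(fixtures)) {
    path <- system.file("extdata", paste0(path_or_fixture_name, ".csv"),
                        package = "grmcat", mustWork = TRUE)
    name <- fixtures[[path_or_fixture_name]]
  } else {
    path <- path_or_fixture_name
    if (!file.exists(path)) {
      stop("no such fixture or file: ", path, call. = FALSE)
    }
    name <- sub("\\.(csv|json)$", "", basename(path))
  }
  items <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    as.data.frame(jsonlite::fromJSON(path))
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  item_bank(items, name = name)
}

#' Write an item bank to CSV or JSON
#'
#' @param bank an `item_bank`.
#' @param path output path ending in `.csv` or `.json`.
#' @return `path`, invisibly.
#' @export
write_item_bank <- function(bank, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(bank$items, path, digits = NA, dataframe = "rows")
  } else {
    utils::write.csv(bank$items, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Construct a response matrix
#'
#' Holds persons-by-items ordinal responses coded 0..4 (`NA` = missing) with
#' optional per-person covariates (`sex`, `age_group`, `sample_type`,
#' `language`, `group`, `true_theta`).
#'
#' @param responses integer matrix, persons in rows, items in columns
#'   (column names are item ids).
#' @param covariates optional data frame with one row per person.
#' @param n_categories number of ordered categories (5).
#' @return object of class `response_matrix`.
#' @export
response_matrix <- function(responses, covariates = NULL, n_categories = 5L) {
  responses <- as.matrix(responses)
  storage.mode(responses) <- "integer"
  vals <- responses[!is.na(responses)]
  if (length(vals) && (min(vals) < 0L || max(vals) > n_categories - 1L)) {
    bad <- which(!is.na(responses) &
                   (responses < 0L | responses > n_categories - 1L),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf("response out of range 0..%d at row %d, column %d",
                 n_categories - 1L, bad[1L], bad[2L]), call. = FALSE)
  }
  if (is.null(rownames(responses)) || anyDuplicated(rownames(responses))) {
    rownames(responses) <- paste0("p", seq_len(nrow(responses)))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    stopifnot(nrow(covariates) == nrow(responses))
    rownames(covariates) <- rownames(responses)
  }
  structure(list(responses = responses, covariates = covariates,
                 n_categories = as.integer(n_categories)),
            class = "response_matrix")
}

#' @export
print.response_matrix <- function(x, ...) {
  cat(sprintf("<response_matrix> %d persons x %d items, %.1f%% missing\n",
              nrow(x$responses), ncol(x$responses),
              100 * missing_fraction(x)))
  invisible(x)
}

#' @export
dim.response_matrix <- function(x) dim(x$responses)

#' Fraction of missing responses
#' @param matrix a `response_matrix`.
#' @return proportion of cells that are `NA`.
#' @export
missing_fraction <- function(matrix) {
  mean(is.na(matrix$responses))
}

#' Read a response CSV
#'
#' The file has a header of item ids; reserved columns (`person_id`, `sex`,
#' `age_group`, `sample_type`, `language`, `group`, `true_theta`) are split
#' off as covariates. Empty cells are missing. The `one_based` dialect codes
#' categories 1..5 on disk and is shifted to the internal 0..4 coding.
#'
#' @param path CSV path.
#' @param dialect `"zero_based"` (0..4 on disk) or `"one_based"` (1..5).
#' @param bank optional `item_bank`; if given, file columns are checked and
#'   reordered against it.
#' @return `response_matrix`.
#' @export
read_responses <- function(path, dialect = c("zero_based", "one_based"),
                           bank = NULL) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  cov_cols <- intersect(.covariate_cols, names(df))
  item_cols <- setdiff(names(df), cov_cols)
  if (!is.null(bank)) {
    unknown <- setdiff(item_cols, item_ids(bank))
    if (length(unknown) > 0L) {
      stop("column(s) not in bank '", bank$name, "': ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    absent <- setdiff(item_ids(bank), item_cols)
    if (length(absent) > 0L) {
      stop("bank item(s) absent from file: ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    item_cols <- item_ids(bank)
  }
  resp <- as.matrix(df[item_cols])
  storage.mode(resp) <- "integer"
  lo <- if (dialect == "one_based") 1L else 0L
  out_of_range <- which(!is.na(resp) & (resp < lo | resp > lo + 4L),
                        arr.ind = TRUE)
  if (nrow(out_of_range) > 0L) {
    stop(sprintf("response %d outside %d..%d at row %d, column '%s'",
                 resp[out_of_range[1L, , drop = FALSE]],
                 lo, lo + 4L, out_of_range[1L, 1L],
                 item_cols[out_of_range[1L, 2L]]), call. = FALSE)
  }
  if (dialect == "one_based") resp <- resp - 1L
  cov <- if (length(cov_cols)) df[cov_cols] else NULL
  if (!is.null(cov) && "person_id" %in% names(cov)) {
    rownames(resp) <- as.character(cov$person_id)
  }
  response_matrix(resp, covariates = cov)
}

#' Write a response matrix to CSV
#'
#' Inverse of [read_responses()]; missing cells are written empty.
#'
#' @inheritParams read_responses
#' @param matrix a `response_matrix`.
#' @return `path`, invisibly.
#' @export
write_responses <- function(matrix, path,
                            dialect = c("zero_based", "one_based")) {
  dialect <- match.arg(dialect)
  resp <- matrix$responses
  if (dialect == "one_based") resp <- resp + 1L
  df <- as.data.frame(resp)
  if (!is.null(matrix$covariates)) df <- cbind(matrix$covariates, df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Listwise-complete subset of a response matrix
#'
#' Drops every person with at least one missing response, mirroring listwise
#' deletion per item bank; the removed fraction is attached as attribute
#' `"fraction_removed"`.
#'
#' @param matrix a `response_matrix`.
#' @return complete-case `response_matrix`.
#' @export
listwise_complete <- function(matrix) {
  keep <- stats::complete.cases(matrix$responses)
  if (!any(keep)) {
    stop("empty sample: every person has at least one missing response",
         call. = FALSE)
  }
  out <- response_matrix(matrix$responses[keep, , drop = FALSE],
                         covariates = if (is.null(matrix$covariates)) NULL
                         else matrix$covariates[keep, , drop = FALSE],
                         n_categories = matrix$n_categories)
  attr(out, "fraction_removed") <- mean(!keep)
  out
}
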