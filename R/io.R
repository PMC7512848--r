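# Validate a count vector: nonnegative integers, not all zero.
.validate_counts <- function(counts, k = NULL) {
  x <- suppressWarnings(as.numeric(counts))
  if (any(is.na(x))) stop("counts contain missing or non-numeric values")
  if (any(x < 0)) stop("counts must be nonnegative")
  if (any(abs(x - round(x)) > 0)) stop("counts must be exact integers")
  if (sum(x) < 1) stop("counts must not be all zero")
  if (!is.null(k) && length(x) != k)
    stop("expected ", k, " cells, got ", length(x))
  structure(as.integer(round(x)), names = names(counts))
}

#' Read a multinomial count table
#'
#' Accepts a two-column TSV/CSV file (header, columns label and count), a
#' JSON object mapping label to count, or an inline comma-separated string
#' such as \code{"165,13,7,0"}.  Counts must be exact nonnegative integers;
#' duplicate labels are rejected.  Cells are identified positionally by the
#' models, so labels are carried as metadata only.
#'
#' @param x Path to a file, or an inline comma-separated count string.
#' @param format One of \code{"tsv"}, \code{"csv"}, \code{"json"};
#'   guessed from the file extension when \code{NULL}.
#' @return Named integer vector of class \code{count_vector}.
#' @examples
#' read_counts("165,13,7,0")
#' @export
read_counts <- function(x, format = NULL) {
  stopifnot(is.character(x), length(x) == 1L)
  if (!file.exists(x)) {
    if (grepl(",", x)) {
      parts <- trimws(strsplit(x, ",")[[1]])
      num <- suppressWarnings(as.numeric(parts))
      if (any(is.na(num)))
        stop("cannot parse inline counts '", x, "'")
      return(structure(.validate_counts(num), class = "count_vector"))
    }
    stop("file not found: ", x)
  }
  if (is.null(format))
    format <- tolower(tools::file_ext(x))
  counts <- switch(format,
    tsv = , txt = .read_counts_table(x, sep = "\t"),
    csv = .read_counts_table(x, sep = ","),
    json = {
      obj <- jsonlite::read_json(x)
      stats::setNames(vapply(obj, function(v) as.numeric(v[[1]]), numeric(1)),
                      names(obj))
    },
    stop("unsupported count-table format '", format, "'"))
  if (anyDuplicated(names(counts)))
    stop("duplicate cell labels in ", x)
  structure(.validate_counts(counts), class = "count_vector")
}

.read_counts_table <- function(path, sep) {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(df) < 2)
    stop("count table must have two columns (label, count): ", path)
  num <- suppressWarnings(as.numeric(df[[2]]))
  bad <- which(is.na(num) | num < 0 | abs(num - round(num)) > 0)
  if (length(bad))
    stop("invalid count at data line ", bad[1], " of ", path, ": '",
         df[[2]][bad[1]], "'")
  stats::setNames(num, df[[1]])
}

#' @export
print.count_vector <- function(x, ...) {
  cat(sprintf("Multinomial counts: k = %d cells, n = %d\n",
              length(x), sum(x)))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Write a count table
#'
#' @param counts Named (or unnamed) nonnegative integer vector.
#' @param path Output path.
#' @param format \code{"tsv"}, \code{"csv"} or \code{"json"}; guessed from
#'   the extension when \code{NULL}.
#' @return \code{path}, invisibly.
#' @export
write_counts <- function(counts, path, format = NULL) {
  counts <- .validate_counts(counts)
  if (is.null(format)) format <- tolower(tools::file_ext(path))
  labels <- names(counts)
  if (is.null(labels)) labels <- paste0("cell", seq_along(counts))
  if (format == "json") {
    jsonlite::write_json(as.list(stats::setNames(as.integer(counts), labels)),
                         path, auto_unbox = TRUE)
  } else {
    sep <- if (format == "csv") "," else "\t"
    utils::write.table(data.frame(label = labels, count = as.integer(counts)),
                       path, sep = sep, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Evergreen Broadleaf Trees classification counts
#'
#' The two worked-example count vectors: classifications of the Evergreen
#' Broadleaf Trees (EBL) land-cover class against the confusion classes
#' Deciduous Broadleaf Trees (DBL), Evergreen Needleleaf Trees (ENL) and
#' Urban/Built Up (U), from the Globcover and LC-CCI global land cover
#' maps.  Both tables have an empty confusion cell, which is why a
#' penalized divergence is needed to fit the Hardy--Weinberg-type model
#' \code{"example3-hw"}.
#'
#' @param map \code{"globcover"} (counts 165, 13, 7, 0) or \code{"lc-cci"}
#'   (172, 5, 5, 0); the fixture aliases \code{"globcover-ebl"} and
#'   \code{"lccci-ebl"} are also accepted.
#' @return Named integer vector of class \code{count_vector}.
#' @examples
#' ebl_counts("globcover")
#' @export
ebl_counts <- function(map = c("globcover", "lc-cci",
                               "globcover-ebl", "lccci-ebl")) {
  map <- match.arg(map)
  file <- switch(map,
                 "globcover" = , "globcover-ebl" = "globcover_ebl.tsv",
                 "lc-cci" = , "lccci-ebl" = "lccci_ebl.tsv")
  read_counts(system.file("extdata", file, package = "pendiv",
                          mustWork = TRUE))
}

#' Relative cell frequencies
#'
#' Maps counts to \eqn{\hat\pi_i = X_i / n}.  The positivity pattern is
#' exact: a cell frequency is zero iff its count is zero.
#'
#' @param counts Nonnegative integer counts, n = sum > 0.
#' @return Numeric probability vector with attributes \code{m} (number of
#'   positive cells) and \code{positive} (logical mask).
#' @export
relative_frequencies <- function(counts) {
  counts <- .validate_counts(counts)
  n <- sum(counts)
  out <- as.numeric(counts) / n
  attr(out, "positive") <- counts > 0
  attr(out, "m") <- sum(counts > 0)
  out
}
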