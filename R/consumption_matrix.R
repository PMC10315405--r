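#' Construct a categorical consumption matrix
#'
#' The observed-data container for the RPC model: an `n x p` integer matrix of
#' consumption levels in `1..d` (level 1 = no consumption) together with a
#' subgroup index per person.
#'
#' @param y Integer matrix, `n x p`, entries in `1..d`. No missing values:
#'   upstream preprocessing must resolve them.
#' @param subgroup Integer vector of length `n` with values in `1..S`, or a
#'   factor (levels become subgroup names).
#' @param d Number of consumption levels (default 4).
#' @param items Optional character vector of `p` item names.
#' @param subgroups Optional character vector of `S` subgroup names.
#' @return An object of class `consumption_matrix`: a list with elements `y`,
#'   `subgroup`, `d`, `items`, `subgroups`, `n`, `p`, `S`.
#' @export
consumption_matrix <- function(y, subgroup, d = 4L, items = NULL,
                               subgroups = NULL) {
  y <- as.matrix(y)
  storage.mode(y) <- "integer"
  if (is.factor(subgroup)) {
    if (is.null(subgroups)) subgroups <- levels(subgroup)
    subgroup <- as.integer(subgroup)
  }
  subgroup <- as.integer(subgroup)
  n <- nrow(y); p <- ncol(y)
  if (length(subgroup) != n)
    stop("length(subgroup) must equal nrow(y)", call. = FALSE)
  if (anyNA(y) || anyNA(subgroup))
    stop("consumption matrix must not contain missing values", call. = FALSE)
  if (any(y < 1L) || any(y > d))
    stop("consumption levels must lie in 1..d", call. = FALSE)
  S <- max(subgroup)
  if (any(subgroup < 1L))
    stop("subgroup indices must lie in 1..S", call. = FALSE)
  if (any(tabulate(subgroup, S) == 0L))
    stop("every subgroup must be nonempty", call. = FALSE)
  if (is.null(items)) items <- colnames(y)
  if (is.null(items)) items <- paste0("item", seq_len(p))
  if (is.null(subgroups)) subgroups <- paste0("subgroup", seq_len(S))
  colnames(y) <- items
  structure(
    list(y = y, subgroup = subgroup, d = as.integer(d), items = items,
         subgroups = subgroups, n = n, p = p, S = S),
    class = "consumption_matrix")
}

#' @export
print.consumption_matrix <- function(x, ...) {
  cat(sprintf("consumption_matrix: %d persons x %d items, %d levels, %d subgroups\n",
              x$n, x$p, x$d, x$S))
  tab <- table(factor(x$subgroup, seq_len(x$S), labels = x$subgroups))
  print(tab)
  invisible(x)
}

#' Write / read a consumption matrix as CSV
#'
#' One row per person: `id`, `subgroup` (name), then one `y_<item>` column per
#' food item holding the integer level.
#'
#' @param x A `consumption_matrix`.
#' @param path File path.
#' @return `write_consumption` returns `path` invisibly; `read_consumption`
#'   returns a `consumption_matrix`.
#' @export
write_consumption <- function(x, path) {
  df <- data.frame(id = seq_len(x$n),
                   subgroup = x$subgroups[x$subgroup],
                   x$y, check.names = FALSE)
  names(df)[-(1:2)] <- paste0("y_", x$items)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_consumption
#' @param d Number of consumption levels expected in the file.
#' @export
read_consumption <- function(path, d = 4L) {
  df <- read.csv(path, check.names = FALSE)
  ycols <- grep("^y_", names(df), value = TRUE)
  y <- as.matrix(df[ycols])
  sub <- factor(df$subgroup, levels = unique(df$subgroup))
  consumption_matrix(y, sub, d = d, items = sub("^y_", "", ycols))
}
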