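#' Canonical HoNOS65+ clustering items
#'
#' The nine HoNOS65+ items used as clustering variables: item 1 (behavioural
#' disturbance), items 4-10 (cognitive problems; physical illness/disability;
#' hallucinations and delusions; depressive symptoms; other mental and
#' behavioural problems; social or supportive relationships; activities of
#' daily living) and item 13 (drug management).  Items 2 and 3 (self-injury,
#' drinking/drug use) are rare in advanced dementia and items 11 and 12
#' concern community living conditions, so none of them enter the clustering.
#'
#' @return Character vector of the nine canonical item labels, in the fixed
#'   order used for all centroid output.
#' @export
#' @examples
#' rating_items()
rating_items <- function() {
  c("HoNOS-1", paste0("HoNOS-", 4:10), "HoNOS-13")
}

#' Display names of the four canonical BPSD profiles
#'
#' Profile order matches the reference centroids of [reference_centroids()]:
#' affective, functional, somatic, psychotic.
#'
#' @return Character vector of length 4.
#' @export
profile_names <- function() {
  c("BPSD-affective", "BPSD-functional", "BPSD-somatic", "BPSD-psychotic")
}

#' Reference profile centroids
#'
#' Mean item scores of the four BPSD profiles in the reference cohort of 542
#' psychogeriatric inpatients (profiles sized 233/95/137/77).  These centroids
#' parameterize the default synthetic cohort and anchor profile naming in
#' [label_profiles()].
#'
#' @return A 4 x 9 numeric matrix, rows named by [profile_names()], columns by
#'   [rating_items()].
#' @export
#' @examples
#' reference_centroids()["BPSD-psychotic", "HoNOS-6"]
reference_centroids <- function() {
  m <- rbind(
    c(1.61, 2.94, 1.74, 0.74, 1.59, 2.27, 1.42, 2.28, 0.12),
    c(1.38, 2.80, 1.62, 0.46, 1.15, 1.35, 1.01, 2.59, 2.86),
    c(2.64, 3.39, 3.18, 0.20, 1.56, 2.86, 2.74, 3.32, 2.82),
    c(2.65, 3.26, 2.12, 3.22, 2.10, 2.57, 2.94, 3.08, 2.78)
  )
  dimnames(m) <- list(profile_names(), rating_items())
  m
}

## Validate an ordinal score block; returns a logical vector of valid rows
## plus the coordinates of offending cells.
validate_scores <- function(x) {
  bad <- is.na(x) | x != floor(x) | x < 0 | x > 4
  list(ok = rowSums(bad) == 0L, cells = which(bad, arr.ind = TRUE))
}

#' Read an ordinal rating table
#'
#' Reads a comma-separated file of HoNOS65+ item scores (header row mandatory,
#' one row per subject), restricts it to the requested clustering items in
#' canonical order, and validates every score against the 5-point ordinal
#' scale (integers 0-4, no missing values).  Rows failing validation -- the
#' assessment was incomplete or mis-scored -- are reported and excluded, the
#' same all-or-nothing handling applied to incomplete assessments in the
#' reference cohort.
#'
#' @param path Path to a CSV file with a header naming the items; an optional
#'   `subject_id` column supplies subject identifiers (must be unique).
#' @param items Character vector of item columns to keep, in the order they
#'   should appear; defaults to the nine canonical items of [rating_items()].
#' @param quiet Suppress the exclusion report message.
#' @return An integer score matrix (subjects x items) with subject identifiers
#'   as row names and attribute `n_excluded` recording how many rows were
#'   dropped at validation.
#' @seealso [write_ratings()], [check_sample_size()]
#' @export
read_ratings <- function(path, items = rating_items(), quiet = FALSE) {
  stopifnot(length(items) >= 2L)
  d <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(items, names(d))
  if (length(missing_cols))
    stop("rating file ", path, " lacks required item column(s): ",
         paste(missing_cols, collapse = ", "))
  ids <- if ("subject_id" %in% names(d)) as.character(d$subject_id)
         else sprintf("S%04d", seq_len(nrow(d)))
  if (anyDuplicated(ids))
    stop("duplicated subject_id values in ", path)
  x <- as.matrix(d[items])
  storage.mode(x) <- "double"
  v <- validate_scores(x)
  if (nrow(v$cells)) {
    coords <- apply(v$cells, 1L, function(rc)
      sprintf("row %d (%s), item %s", rc[1L], ids[rc[1L]], items[rc[2L]]))
    warning(sum(!v$ok), " row(s) excluded; invalid scores at: ",
            paste(utils::head(coords, 10L), collapse = "; "),
            if (length(coords) > 10L) " ..." else "", call. = FALSE)
  }
  if (!quiet)
    message("read ", sum(v$ok), " subjects x ", length(items), " items (",
            sum(!v$ok), " row(s) excluded)")
  x <- x[v$ok, , drop = FALSE]
  storage.mode(x) <- "integer"
  rownames(x) <- ids[v$ok]
  structure(x, n_excluded = sum(!v$ok))
}

#' Write an ordinal rating table
#'
#' Inverse of [read_ratings()]: writes a score matrix as CSV (UTF-8, header
#' row, `subject_id` first column) so that read-write-read round-trips are
#' the identity on valid tables.
#'
#' @param x Score matrix with subject identifiers as row names.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ratings <- function(x, path) {
  d <- data.frame(subject_id = rownames(x) %||% sprintf("S%04d", seq_len(nrow(x))),
                  x, check.names = FALSE)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Sample-size adequacy for cluster analysis
#'
#' Cluster analyses of d variables are commonly sized against simulation-based
#' anchors of 30d-40d subjects (optimal), with 70d as a conservative
#' requirement.  This check reports the multiplier `floor(n / d)` and its
#' category relative to those anchors.
#'
#' @param n Number of subjects (positive).
#' @param d Number of clustering variables (positive).
#' @return An object of class `"sample_size_check"`: list with `n`, `d`,
#'   `multiplier`, and `category` (one of `"below-optimal"` (< 30),
#'   `"optimal"` (30-40), `"adequate"` (41-69), `"conservative"` (>= 70)).
#' @export
#' @examples
#' check_sample_size(542, 9)  # multiplier 60, adequate
check_sample_size <- function(n, d) {
  stopifnot(n > 0, d > 0)
  m <- floor(n / d)
  category <-
    if (m < 30) "below-optimal"
    else if (m <= 40) "optimal"
    else if (m < 70) "adequate"
    else "conservative"
  structure(list(n = n, d = d, multiplier = m, category = category),
            class = "sample_size_check")
}

#' @export
print.sample_size_check <- function(x, ...) {
  cat(sprintf("sample size n = %d for d = %d clustering variables: %dd (%s)\n",
              x$n, x$d, x$multiplier, x$category))
  invisible(x)
}
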