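#' Raw repeated-measures study
#'
#' Container for long-format repeated measures: for each group \eqn{i}, a
#' matrix with one row per subject and \eqn{T} columns of measurements.
#'
#' @param groups a list of numeric matrices, one per group, each with
#'   \eqn{n_i \ge 2} subject rows and the same number \eqn{T} of columns.
#' @param group_names optional character labels; defaults to list names or
#'   \code{"1"}, \code{"2"}, ...
#' @return An object of class \code{"raw_study"}.
#' @seealso [summarize_study()], [read_raw_study()], [generate_dataset()]
#' @export
raw_study <- function(groups, group_names = NULL) {
  if (!is.list(groups) || length(groups) < 1L)
    stop("'groups' must be a non-empty list of matrices")
  groups <- lapply(groups, function(g) {
    g <- as.matrix(g)
    storage.mode(g) <- "double"
    g
  })
  T <- ncol(groups[[1L]])
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    if (ncol(g) != T)
      stop("all groups must have the same number of repeated measurements T")
    if (nrow(g) < 2L)
      stop(sprintf("group %d has fewer than 2 subjects", k))
    if (any(!is.finite(g)))
      stop(sprintf("group %d contains non-finite observations", k))
  }
  if (is.null(group_names)) group_names <- names(groups)
  if (is.null(group_names)) group_names <- as.character(seq_along(groups))
  names(groups) <- group_names
  structure(list(groups = groups, T = as.integer(T)), class = "raw_study")
}

#' @export
print.raw_study <- function(x, ...) {
  n <- vapply(x$groups, nrow, 0L)
  cat(sprintf("Raw repeated-measures study: %d groups, T = %d repeats\n",
              length(n), x$T))
  cat("  n:", paste(n, collapse = " "), "\n")
  invisible(x)
}

#' Per-group sufficient statistics
#'
#' Every test and interval procedure in the package depends on the data only
#' through the per-group triple \eqn{(n_i, \hat\mu_i, S_i^2)} and the repeat
#' count \eqn{T}: \eqn{\hat\mu_i} is the mean over subjects of the subject
#' means \eqn{\bar Y_{ij\cdot}}, and
#' \eqn{S_i^2 = T \sum_j (\bar Y_{ij\cdot} - \bar Y_{i\cdot\cdot})^2} is the
#' between-subject residual sum of squares, scaled so that
#' \eqn{S_i^2/\phi_i^2 \sim \chi^2_{n_i-1}}.
#'
#' @param n integer vector of subject counts \eqn{n_i} (each >= 2).
#' @param mu_hat numeric vector of group means \eqn{\hat\mu_i}.
#' @param ss numeric vector of residual sums of squares \eqn{S_i^2}
#'   (nonnegative; the tests require them strictly positive).
#' @param T repeats per subject.
#' @param group_names optional labels.
#' @return An object of class \code{"study_summary"}.
#' @seealso [summarize_study()] to reduce raw data, [gf_test()], [sp_test()],
#'   [pb_test()], [gpq_simultaneous_ci()], [pb_simultaneous_ci()]
#' @examples
#' study_summary(n = c(5, 5), mu_hat = c(1.2, 0.4), ss = c(10.3, 12.8), T = 4)
#' @export
study_summary <- function(n, mu_hat, ss, T, group_names = NULL) {
  I <- length(n)
  if (I < 2L) stop("at least two groups are required")
  if (length(mu_hat) != I || length(ss) != I)
    stop("'n', 'mu_hat' and 'ss' must have equal length")
  n <- as.integer(n)
  if (any(n < 2L)) stop("every group needs n_i >= 2")
  if (any(!is.finite(mu_hat))) stop("'mu_hat' must be finite")
  if (any(!is.finite(ss)) || any(ss < 0)) stop("'ss' must be nonnegative")
  T <- as.integer(T)
  if (length(T) != 1L || T < 1L) stop("'T' must be a single integer >= 1")
  if (is.null(group_names)) group_names <- as.character(seq_len(I))
  structure(list(n = n, mu_hat = as.numeric(mu_hat), ss = as.numeric(ss),
                 T = T, group_names = as.character(group_names)),
            class = "study_summary")
}

as_study_summary <- function(x) {
  if (inherits(x, "study_summary")) return(x)
  if (inherits(x, "raw_study")) return(summarize_study(x))
  stop("expected a 'study_summary' or 'raw_study' object")
}

#' @export
print.study_summary <- function(x, ...) {
  cat(sprintf("Study summary: %d groups, T = %d repeats, N = %d subjects\n",
              length(x$n), x$T, sum(x$n)))
  print(data.frame(group = x$group_names, n = x$n,
                   mu_hat = x$mu_hat, ss = x$ss), row.names = FALSE)
  invisible(x)
}

#' Reduce raw data to sufficient statistics
#'
#' @param raw a [raw_study] object.
#' @return A [study_summary] with
#'   \eqn{\hat\mu_i = \frac1{n_i}\sum_j \bar Y_{ij\cdot}} and
#'   \eqn{S_i^2 = T\sum_j(\bar Y_{ij\cdot} - \bar Y_{i\cdot\cdot})^2}.
#' @examples
#' rs <- raw_study(list(a = rbind(c(1, 3), c(3, 5))))
#' # single group not allowed for tests, but reduction works groupwise:
#' @export
summarize_study <- function(raw) {
  if (!inherits(raw, "raw_study")) stop("expected a 'raw_study' object")
  T <- raw$T
  n <- vapply(raw$groups, nrow, 0L)
  mu_hat <- numeric(length(n))
  ss <- numeric(length(n))
  for (k in seq_along(raw$groups)) {
    sm <- rowMeans(raw$groups[[k]])        # subject means
    mu_hat[k] <- mean(sm)
    ss[k] <- T * sum((sm - mu_hat[k])^2)
  }
  out <- study_summary(n, mu_hat, ss, T, group_names = names(raw$groups))
  out
}

#' Read raw repeated-measures data from CSV
#'
#' Two layouts are supported. Long format has columns
#' \code{group,subject,t,value} with \code{t} running 1..T; wide format has
#' columns \code{group,subject,y1,...,yT}.
#'
#' @param path file path.
#' @param format \code{"long"} or \code{"wide"}.
#' @return A [raw_study].
#' @export
read_raw_study <- function(path, format = c("long", "wide")) {
  format <- match.arg(format)
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (nrow(d) == 0L) stop("no data rows in ", path)
  if (format == "long") {
    need <- c("group", "subject", "t", "value")
    miss <- setdiff(need, names(d))
    if (length(miss))
      stop("long-format file lacks column(s): ", paste(miss, collapse = ", "))
    T <- max(d$t)
    if (!all(sort(unique(d$t)) == seq_len(T)))
      stop("column 't' must cover 1..T")
    groups <- lapply(split(d, d$group), function(g) {
      m <- t(vapply(split(g, g$subject), function(s) {
        if (nrow(s) != T || anyDuplicated(s$t))
          stop("subject ", s$subject[1L], " in group ", s$group[1L],
               " does not have exactly one value for each t in 1..", T)
        s$value[order(s$t)]
      }, numeric(T)))
      m
    })
  } else {
    ycols <- grep("^y[0-9]+$", names(d), value = TRUE)
    if (!all(c("group", "subject") %in% names(d)) || length(ycols) == 0L)
      stop("wide-format file needs columns group, subject, y1..yT")
    ycols <- ycols[order(as.integer(sub("^y", "", ycols)))]
    groups <- lapply(split(d, d$group), function(g) as.matrix(g[, ycols]))
  }
  raw_study(groups)
}

#' Read per-group summary statistics from CSV
#'
#' Expects columns \code{group,n,mu_hat,ss}. The repeat count \eqn{T} may be
#' given as the argument \code{T} or as a header comment line of the form
#' \code{# T: 4}.
#'
#' @param path file path.
#' @param T repeats per subject; if \code{NULL}, taken from the header
#'   comment.
#' @return A [study_summary].
#' @export
read_study_summary <- function(path, T = NULL) {
  if (is.null(T)) {
    head_lines <- readLines(path, n = 10L)
    tl <- grep("^#\\s*T\\s*[:=]", head_lines, value = TRUE)
    if (length(tl) == 0L)
      stop("'T' not supplied and no '# T: <int>' header comment found")
    T <- as.integer(sub("^#\\s*T\\s*[:=]\\s*", "", tl[1L]))
  }
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("group", "n", "mu_hat", "ss")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("summary file lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(d) == 0L) stop("no data rows in ", path)
  study_summary(d$n, d$mu_hat, d$ss, T, group_names = d$group)
}

#' Example summary data: eight treatments with strongly unequal variances
#'
#' Per-group sufficient statistics of a simulated eight-treatment
#' repeated-measures study (T = 4 measurements per subject) generated from
#' the equicorrelated model with all true means equal to 1, error SDs
#' increasing from 1.0 to 4.5 in steps of 0.5, equicorrelation 0.2 and
#' random-effect SD 1, so every hypothesis of equality among a subset of the
#' treatment means is true.  Useful for exercising the tests under strong
#' heteroscedasticity: the nuisance scales \eqn{\phi_i^2} range from 5.6 to
#' 36.4.
#'
#' @return A [study_summary] with groups labelled A through H.
#' @examples
#' s <- example_study_summary()
#' gf_test(s, mc_samples = 10000, seed = 1)
#' @export
example_study_summary <- function() {
  path <- system.file("extdata", "eight_treatments.csv",
                      package = "equianova", mustWork = TRUE)
  read_study_summary(path)
}

#' Restrict a summary to a subset of groups
#'
#' @param summary a [study_summary] (or [raw_study], reduced first).
#' @param idx integer positions or character group labels to keep, in order.
#' @return A [study_summary] for the selected groups.
#' @examples
#' subset_groups(example_study_summary(), c("A", "B", "C"))
#' @export
subset_groups <- function(summary, idx) {
  summary <- as_study_summary(summary)
  if (is.character(idx)) idx <- match(idx, summary$group_names)
  if (any(is.na(idx))) stop("unknown group label")
  study_summary(summary$n[idx], summary$mu_hat[idx], summary$ss[idx],
                summary$T, group_names = summary$group_names[idx])
}
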