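#' Sample fixed-margin random tables (Patefield's algorithm)
#'
#' Draws random non-negative integer tables with prescribed row and column
#' margins from the multiple-hypergeometric distribution — the distribution
#' of a table under independence conditional on its margins. Cells are
#' filled row-wise, each drawn from its exact conditional distribution given
#' the margins still unallocated, using log-factorial weights (Patefield
#' 1981, algorithm AS 159). This is the null ensemble used by
#' [permutation_test()] to judge whether behavioural transitions occur more
#' or less often than chance.
#'
#' @param row_margins,col_margins non-negative integer vectors with equal
#'   sums.
#' @param n_null number of tables to draw (the permutation analyses default
#'   to 100000; 0 gives a valid empty ensemble).
#' @param seed optional integer seed; a fixed seed yields an identical
#'   ensemble.
#' @return an object of class `patefield_ensemble`: a list with `matrices`
#'   (integer array of dim `c(nrow, ncol, n_null)`), `n_null`, `seed`,
#'   `row_margins` and `col_margins`.
#' @references Patefield, W. M. (1981). Algorithm AS 159: An efficient
#'   method of generating random R x C tables with given row and column
#'   totals. Applied Statistics 30, 91-97.
#' @examples
#' ens <- patefield_sample(c(2, 1), c(1, 2), 100, seed = 1)
#' all(apply(ens$matrices, 3, rowSums) == c(2, 1))
#' @export
patefield_sample <- function(row_margins, col_margins, n_null, seed = NULL) {
  check_margins(row_margins, col_margins)
  if (n_null < 0) stop("n_null must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  mats <- if (n_null == 0) {
    array(integer(0), dim = c(length(row_margins), length(col_margins), 0))
  } else {
    rcpp_patefield(as.integer(row_margins), as.integer(col_margins),
                   as.integer(n_null))
  }
  dimnames(mats) <- c(margin_dimnames(row_margins, col_margins), list(NULL))
  structure(list(matrices = mats, n_null = as.integer(n_null), seed = seed,
                 row_margins = row_margins, col_margins = col_margins),
            class = "patefield_ensemble")
}

check_margins <- function(row_margins, col_margins) {
  if (any(row_margins < 0) || any(col_margins < 0)) {
    stop("margins must be non-negative")
  }
  if (any(row_margins != round(row_margins)) || any(col_margins != round(col_margins))) {
    stop("margins must be integers")
  }
  if (sum(row_margins) != sum(col_margins)) {
    stop("row margin sum (", sum(row_margins), ") != column margin sum (",
         sum(col_margins), ")")
  }
  invisible(TRUE)
}

margin_dimnames <- function(row_margins, col_margins) {
  list(names(row_margins), names(col_margins))
}

#' @export
print.patefield_ensemble <- function(x, ...) {
  cat(sprintf("Patefield null ensemble: %d tables, %d x %d, total N = %d\n",
              x$n_null, length(x$row_margins), length(x$col_margins),
              sum(x$row_margins)))
  invisible(x)
}

#' Exact distribution of tables with fixed margins
#'
#' Exhaustively enumerates every non-negative integer table with the given
#' margins and evaluates its multiple-hypergeometric probability
#' `P(a) = (prod r_i! prod c_j!) / (N! prod a_ij!)`. Intended as a small-N
#' oracle against which the Monte-Carlo sampler can be checked; refuses
#' totals above `max_total`.
#'
#' @inheritParams patefield_sample
#' @param max_total refuse enumeration when the table total exceeds this
#'   (default 12).
#' @return a list with one element per table: `list(table =, prob =)`.
#'   Probabilities sum to 1.
#' @export
exact_table_distribution <- function(row_margins, col_margins, max_total = 12) {
  check_margins(row_margins, col_margins)
  N <- sum(row_margins)
  if (N > max_total) {
    stop("table total ", N, " exceeds the enumeration limit ", max_total)
  }
  nr <- length(row_margins); nc <- length(col_margins)
  lognum <- sum(lfactorial(row_margins)) + sum(lfactorial(col_margins)) - lfactorial(N)

  out <- list()
  tab <- matrix(0L, nr, nc)
  colrem <- as.integer(col_margins)

  fill_row <- function(i, j, r) {
    if (j == nc) {
      if (r <= colrem[nc]) {
        tab[i, nc] <<- r
        colrem[nc] <<- colrem[nc] - r
        recurse(i + 1L)
        colrem[nc] <<- colrem[nc] + r
      }
      return(invisible(NULL))
    }
    for (a in 0:min(r, colrem[j])) {
      tab[i, j] <<- a
      colrem[j] <<- colrem[j] - a
      fill_row(i, j + 1L, r - a)
      colrem[j] <<- colrem[j] + a
    }
  }
  recurse <- function(i) {
    if (i > nr) {
      p <- exp(lognum - sum(lfactorial(tab)))
      t2 <- tab
      dimnames(t2) <- margin_dimnames(row_margins, col_margins)
      out[[length(out) + 1L]] <<- list(table = t2, prob = p)
      return(invisible(NULL))
    }
    fill_row(i, 1L, as.integer(row_margins[i]))
  }
  recurse(1L)
  out
}
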