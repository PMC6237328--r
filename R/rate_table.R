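#' Age- and sex-indexed rate tables
#'
#' A `rate_table` holds one epidemiological quantity (a rate per person-year,
#' a probability, or a fraction) on an integer age grid `0..a_max`, stratified
#' by sex.  Internally it is a 2 x (a_max + 1) numeric matrix with rows
#' `male`/`female` and columns named by age; all model quantities (prevalence,
#' incidence, attributable mortality, relative risks, ...) use this container.
#'
#' @param values numeric matrix with 2 rows (male, female) and one column per
#'   age `0..a_max`, or a single numeric vector recycled to both sexes.
#' @param quantity short name of the quantity stored (for messages and files).
#' @param a_max highest age of the grid; required when `values` is scalar.
#' @return an object of class `rate_table`.
#' @examples
#' rt <- rate_table_constant(0.02, a_max = 95, quantity = "incidence")
#' rt_value(rt, "female", 50)
#' @export
rate_table <- function(values, quantity = "rate", a_max = NULL) {
  if (is.null(dim(values))) {
    if (!is.null(a_max) && length(values) == 1L) {
      values <- rep(values, a_max + 1L)
    }
    values <- rbind(male = values, female = values)
  }
  values <- as.matrix(values)
  if (nrow(values) != 2L) stop("rate_table needs 2 rows (male, female)")
  rownames(values) <- c("male", "female")
  colnames(values) <- as.character(seq_len(ncol(values)) - 1L)
  storage.mode(values) <- "double"
  structure(values, class = c("rate_table", "matrix"),
            quantity = as.character(quantity))
}

#' @rdname rate_table
#' @export
rate_table_constant <- function(values, a_max, quantity = "rate") {
  rate_table(matrix(values, nrow = 2L, ncol = a_max + 1L),
             quantity = quantity)
}

#' Build a rate table from a function of age
#'
#' @param f function of integer age returning a value; called separately per
#'   sex when `by_sex = TRUE`, in which case `f(age, sex)` is used.
#' @param a_max highest age.
#' @param quantity quantity name.
#' @param by_sex if `TRUE`, `f` takes `(age, sex)`.
#' @return a `rate_table`.
#' @export
rate_table_from_fn <- function(f, a_max, quantity = "rate", by_sex = FALSE) {
  ages <- 0:a_max
  if (by_sex) {
    vals <- rbind(male = vapply(ages, f, numeric(1), sex = "male"),
                  female = vapply(ages, f, numeric(1), sex = "female"))
  } else {
    v <- vapply(ages, f, numeric(1))
    vals <- rbind(male = v, female = v)
  }
  rate_table(vals, quantity = quantity)
}

#' @export
print.rate_table <- function(x, ...) {
  cat(sprintf("<rate_table> %s, ages 0..%d\n", attr(x, "quantity"),
              ncol(x) - 1L))
  a <- unclass(x)
  attr(a, "quantity") <- NULL
  show <- unique(pmin(ncol(a), c(1, 21, 41, 61, 81, ncol(a))))
  print(a[, show, drop = FALSE])
  invisible(x)
}

a_max_of <- function(t) ncol(t) - 1L

#' Look up a rate-table value
#'
#' @param t a `rate_table`.
#' @param sex `"male"` or `"female"`.
#' @param age integer age (0-based).
#' @return numeric value(s).
#' @export
rt_value <- function(t, sex, age) unclass(t)[sex, age + 1L]

#' Cap rates above a given age
#'
#' Replaces all values above `cap` by the value at age `cap`, the standard
#' treatment for sparse disease data at high ages (rates above age 87 are
#' conventionally held at their age-87 value).
#'
#' @param t a `rate_table`.
#' @param cap integer cap age; values at ages `> cap` are set to the value at
#'   `cap`.  Must lie on the table's age grid.
#' @return a `rate_table` of the same shape.
#' @examples
#' rt <- rate_table(rbind(0:95, 0:95) / 100, quantity = "x")
#' rt_value(cap_rates_above_age(rt, 87), "male", 95)  # 0.87
#' @export
cap_rates_above_age <- function(t, cap) {
  amax <- a_max_of(t)
  if (cap > amax) stop("cap beyond table range")
  if (cap < amax) {
    m <- unclass(t)
    m[, (cap + 2L):(amax + 1L)] <- m[, cap + 1L]
    t <- rate_table(m, quantity = attr(t, "quantity"))
  }
  t
}

#' Read / write rate tables as long CSV
#'
#' The on-disk format is a long table with columns `sex,age,value`, one file
#' per quantity, UTF-8 with a header row.
#'
#' @param path file path.
#' @param quantity quantity name to attach on read.
#' @return `read_rate_table` returns a `rate_table`; `write_rate_table`
#'   returns `path` invisibly.
#' @export
read_rate_table <- function(path, quantity = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sex", "age", "value")
  if (!all(need %in% names(df))) {
    stop(sprintf("rate CSV %s must have columns sex,age,value", path))
  }
  ages <- sort(unique(df$age))
  amax <- max(ages)
  if (!identical(as.integer(ages), 0:amax)) {
    miss <- setdiff(0:amax, ages)
    stop(sprintf("rate CSV %s: missing age rows (first: %d)", path, miss[1]))
  }
  m <- matrix(NA_real_, 2L, amax + 1L, dimnames = list(c("male", "female"), 0:amax))
  for (s in c("male", "female")) {
    sub <- df[df$sex == s, ]
    if (nrow(sub) != amax + 1L) {
      stop(sprintf("rate CSV %s: sex '%s' must cover every age 0..%d", path, s, amax))
    }
    m[s, as.character(sub$age)] <- sub$value
  }
  rate_table(m, quantity = if (is.null(quantity)) basename(path) else quantity)
}

#' @rdname read_rate_table
#' @param t a `rate_table` to write.
#' @export
write_rate_table <- function(t, path) {
  m <- unclass(t)
  df <- data.frame(
    sex = rep(rownames(m), each = ncol(m)),
    age = rep(0:(ncol(m) - 1L), times = 2L),
    # %.17g keeps doubles bit-identical through a read/write round trip
    value = sprintf("%.17g", c(t(m)))
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
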