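#' Build a life table with fast lookup
#'
#' Validates annual death probabilities indexed by sex, single-year age and
#' calendar year, and fills missing interior ages by nearest-age
#' carry-forward (with a warning) so the lookup grid is complete.
#'
#' @param df data.frame with columns sex, age, year, qx in [0, 1].
#' @return an object of class `lifetable`.
#' @export
make_life_table <- function(df) {
  need <- c("sex", "age", "year", "qx")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("life table missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  bad <- which(!is.finite(df$qx) | df$qx < 0 | df$qx > 1)
  if (length(bad)) stop("qx outside [0,1] at row ", bad[1L], call. = FALSE)
  sexes <- sort(unique(df$sex))
  ages <- seq(min(df$age), max(df$age))
  years <- seq(min(df$year), max(df$year))
  arr <- array(NA_real_, dim = c(length(sexes), length(ages), length(years)),
               dimnames = list(sexes, ages, years))
  arr[cbind(match(df$sex, sexes), match(df$age, ages), match(df$year, years))] <- df$qx
  if (anyNA(arr)) {
    warning(sum(is.na(arr)), " missing life-table cell(s) filled by nearest-age carry-forward")
    for (s in seq_along(sexes)) for (y in seq_along(years)) {
      col <- arr[s, , y]
      if (all(is.na(col))) stop("no life-table data for sex ", sexes[s],
                                ", year ", years[y], call. = FALSE)
      known <- which(!is.na(col))
      # carry forward from the nearest known age below; below the first known
      # age, carry the first known value back
      idx <- findInterval(seq_along(col), known)
      idx[idx < 1L] <- 1L
      arr[s, , y] <- col[known[idx]]
    }
  }
  structure(list(table = df[, need], arr = arr, sexes = sexes,
                 ages = ages, years = years), class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Life table: sexes", paste(x$sexes, collapse = ", "),
      "| ages", min(x$ages), "-", max(x$ages),
      "| years", min(x$years), "-", max(x$years), "\n")
  invisible(x)
}

#' Look up annual death probabilities
#'
#' @param lt a `lifetable`.
#' @param sex,age,year vectors (recycled to a common length).
#' @param clamp if TRUE, ages and years outside the table are clamped to the
#'   nearest tabulated value (used by the simulator for very old ages); if
#'   FALSE, out-of-table cells raise an error naming the cell.
#' @return numeric vector of probabilities.
#' @export
q_lookup <- function(lt, sex, age, year, clamp = TRUE) {
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(sex, n); age <- rep_len(age, n); year <- rep_len(year, n)
  si <- match(sex, lt$sexes)
  ai <- age - lt$ages[1L] + 1L
  yi <- year - lt$years[1L] + 1L
  if (clamp) {
    ai <- pmin(length(lt$ages), pmax(1L, ai))
    yi <- pmin(length(lt$years), pmax(1L, yi))
  }
  bad <- is.na(si) | ai < 1L | ai > length(lt$ages) | yi < 1L | yi > length(lt$years)
  if (any(bad)) {
    b <- which(bad)[1L]
    stop("life-table cell not found: (", sex[b], ", ", age[b], ", ", year[b], ")",
         call. = FALSE)
  }
  lt$arr[cbind(si, ai, yi)]
}

read_csv_checked <- function(path, need) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(need, names(df))
  if (length(miss)) stop(path, ": missing column(s) ",
                         paste(miss, collapse = ", "), call. = FALSE)
  df
}

#' Readers and writers for the pipeline's CSV tables
#'
#' Plain UTF-8 CSVs with header rows. Population: sex, age_group, count.
#' Life table: sex, age, year, qx. Cross-sections: year, country, sex,
#' age_group, category, weight. Panel: hh_id, seq, sex, birth_year, year,
#' category, weight. Prevalence: country, sex, age_group, year, category,
#' proportion (optional lower, upper).
#'
#' @param path CSV file path.
#' @param df table to write.
#' @return readers return a data.frame (the life-table reader a `lifetable`);
#'   writers return the path invisibly.
#' @name io_tables
NULL

#' @rdname io_tables
#' @export
read_population <- function(path) {
  df <- read_csv_checked(path, c("sex", "age_group", "count"))
  if (any(df$count < 0)) stop(path, ": negative population count", call. = FALSE)
  df
}

#' @rdname io_tables
#' @export
write_population <- function(df, path) {
  utils::write.csv(df[, c("sex", "age_group", "count")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_life_table <- function(path) {
  make_life_table(read_csv_checked(path, c("sex", "age", "year", "qx")))
}

#' @rdname io_tables
#' @export
write_life_table <- function(df, path) {
  if (inherits(df, "lifetable")) df <- df$table
  utils::write.csv(df[, c("sex", "age", "year", "qx")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_cross_sections <- function(path) {
  read_csv_checked(path, c("year", "country", "sex", "age_group", "category", "weight"))
}

#' @rdname io_tables
#' @export
write_cross_sections <- function(df, path) {
  utils::write.csv(df[, c("year", "country", "sex", "age_group", "category", "weight")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_panel <- function(path) {
  read_csv_checked(path, c("hh_id", "seq", "sex", "birth_year", "year", "category", "weight"))
}

#' @rdname io_tables
#' @export
write_panel <- function(df, path) {
  utils::write.csv(df[, c("hh_id", "seq", "sex", "birth_year", "year", "category", "weight")],
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
write_prevalence <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname io_tables
#' @export
read_prevalence <- function(path) {
  read_csv_checked(path, c("country", "sex", "age_group", "year", "category", "proportion"))
}

parse_ur_cell <- function(cell, where = "") {
  m <- regexec("^\\s*([0-9.]+)\\s*(?:\\(\\s*([0-9.]+)\\s*[–-]\\s*([0-9.]+)\\s*\\))?\\s*$",
               cell)
  g <- regmatches(cell, m)[[1L]]
  if (length(g) < 2L || g[2L] == "")
    stop("malformed transition cell ", where, ": '", cell, "'", call. = FALSE)
  point <- as.numeric(g[2L])
  lo <- if (g[3L] == "") point else as.numeric(g[3L])
  hi <- if (g[4L] == "") point else as.numeric(g[4L])
  c(point = point, lower = lo, upper = hi)
}

#' Read a published-style transition table
#'
#' Parses a CSV whose cells hold percentages with 95% uncertainty ranges in
#' the form `"36.9 (33.2-40.6)"` (en dash or hyphen), one row per (sex,
#' origin), destination columns `d0..d(K-1)`. Points are converted to
#' proportions and rows renormalised via [load_fixed_matrix()].
#'
#' @param path CSV with columns sex, origin, d0, d1, ....
#' @param renormalize passed to [load_fixed_matrix()].
#' @return named list per sex: `matrix` (a renormalised `transition_matrix`),
#'   `point`, `lower`, `upper` (raw proportions, not renormalised).
#' @export
read_transition_table <- function(path, renormalize = TRUE) {
  df <- read_csv_checked(path, c("sex", "origin"))
  dcols <- grep("^d[0-9]+$", names(df), value = TRUE)
  K <- length(dcols)
  if (K < 2L) stop(path, ": no destination columns d0..dK found", call. = FALSE)
  out <- list()
  for (s in unique(df$sex)) {
    block <- df[df$sex == s, ]
    block <- block[order(block$origin), ]
    if (nrow(block) != K) stop(path, ": sex '", s, "' has ", nrow(block),
                               " rows, expected ", K, call. = FALSE)
    pt <- lo <- hi <- matrix(NA_real_, K, K)
    for (i in seq_len(K)) for (j in seq_len(K)) {
      v <- parse_ur_cell(as.character(block[i, dcols[j]]),
                         where = paste0("(sex ", s, ", origin ", block$origin[i],
                                        ", ", dcols[j], ")"))
      pt[i, j] <- v["point"]; lo[i, j] <- v["lower"]; hi[i, j] <- v["upper"]
    }
    out[[s]] <- list(matrix = load_fixed_matrix(pt, renormalize = renormalize),
                     point = pt / 100, lower = lo / 100, upper = hi / 100)
  }
  out
}

#' @rdname io_tables
#' @export
write_transition_table <- function(point, path, lower = NULL, upper = NULL,
                                   sex = "both") {
  K <- nrow(point)
  fmt <- function(i, j) {
    p <- 100 * point[i, j]
    if (is.null(lower)) sprintf("%.4g", p)
    else sprintf("%.4g (%.4g-%.4g)", p, 100 * lower[i, j], 100 * upper[i, j])
  }
  cells <- matrix("", K, K)
  for (i in seq_len(K)) for (j in seq_len(K)) cells[i, j] <- fmt(i, j)
  df <- data.frame(sex = sex, origin = 0:(K - 1L), cells, stringsAsFactors = FALSE)
  names(df) <- c("sex", "origin", paste0("d", 0:(K - 1L)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Path to a bundled example data file
#'
#' @param file file name under the package's `extdata` directory; with no
#'   argument, lists the available files.
#' @return a file path (or a vector of file names).
#' @export
expowin_example <- function(file = NULL) {
  if (is.null(file)) return(dir(system.file("extdata", package = "expowin")))
  system.file("extdata", file, package = "expowin", mustWork = TRUE)
}
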