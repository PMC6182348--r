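#' Read and write abridged life tables as CSV
#'
#' The on-disk schema is a comma-delimited, UTF-8 text file with a header
#' and columns `year`, `sex`, `age_lower`, `age_width`, `exposure`,
#' `deaths` and optionally `qx`. When `qx` is absent it is derived as
#' `deaths / exposure`. Rows are grouped into one [build_life_table()]
#' result per `(year, sex)` pair; each group's rows must tile a
#' contiguous age grid starting at 0. The synthetic generator writes the
#' same schema, so files derived from external abridged tables can be
#' dropped in unchanged.
#'
#' @param path Path to a CSV file.
#' @param radix,a_frac,close_last Passed to [build_life_table()].
#' @return `read_abridged_tables()` returns a list of
#'   `abridged_life_table` objects named `"<year>/<sex>"`, ordered by sex
#'   then year.
#' @export
read_abridged_tables <- function(path, radix = 1e5, a_frac = 0.5,
                                 close_last = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("year", "sex", "age_lower", "age_width", "exposure", "deaths")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("file '%s' is missing required columns: %s",
                 path, paste(missing_cols, collapse = ", ")))
  }
  df$.row <- seq_len(nrow(df)) + 1L  # header is line 1
  if (any(df$deaths > df$exposure + 1e-9)) {
    bad <- df$.row[which(df$deaths > df$exposure + 1e-9)[1L]]
    stop(sprintf(
      "row %d of '%s': deaths exceed exposure (implied q > 1)", bad, path
    ))
  }
  if (!"qx" %in% names(df)) {
    if (any(df$exposure <= 0)) {
      bad <- df$.row[which(df$exposure <= 0)[1L]]
      stop(sprintf(
        "row %d of '%s': non-positive exposure and no qx column", bad, path
      ))
    }
    df$qx <- df$deaths / df$exposure
  }
  if (any(df$qx < 0 | df$qx > 1)) {
    bad <- df$.row[which(df$qx < 0 | df$qx > 1)[1L]]
    stop(sprintf("row %d of '%s': qx outside [0, 1]", bad, path))
  }

  keys <- unique(df[, c("sex", "year")])
  keys <- keys[order(keys$sex, keys$year), , drop = FALSE]
  tables <- vector("list", nrow(keys))
  names(tables) <- paste0(keys$year, "/", keys$sex)
  for (i in seq_len(nrow(keys))) {
    block <- df[df$year == keys$year[i] & df$sex == keys$sex[i], , drop = FALSE]
    block <- block[order(block$age_lower), , drop = FALSE]
    ends <- block$age_lower + block$age_width
    gap <- which(abs(block$age_lower[-1L] - ends[-nrow(block)]) > 1e-9)
    if (block$age_lower[1L] != 0) {
      stop(sprintf(
        "year %s, sex %s in '%s': first age group must start at 0",
        keys$year[i], keys$sex[i], path
      ))
    }
    if (length(gap) > 0L) {
      g <- gap[1L]
      stop(sprintf(
        "year %s, sex %s in '%s' (row %d): age groups not contiguous, gap between %g and %g",
        keys$year[i], keys$sex[i], path, block$.row[g + 1L],
        ends[g], block$age_lower[g + 1L]
      ))
    }
    grid <- age_grid(block$age_lower, block$age_width)
    tables[[i]] <- build_life_table(
      q = block$qx, grid = grid, radix = radix, a_frac = a_frac,
      year = keys$year[i], sex = keys$sex[i],
      E = block$exposure, d_obs = block$deaths, close_last = close_last
    )
  }
  tables
}

#' @rdname read_abridged_tables
#' @param tables A list of `abridged_life_table` objects (each needing
#'   `E` and `d_obs` columns).
#' @return `write_abridged_tables()` invisibly returns `path`. A
#'   write-then-read round trip reproduces `q`, `E` and `d_obs` to 12
#'   significant digits.
#' @export
write_abridged_tables <- function(tables, path) {
  if (inherits(tables, "abridged_life_table")) tables <- list(tables)
  rows <- lapply(tables, function(lt) {
    if (!inherits(lt, "abridged_life_table")) {
      stop("all elements of 'tables' must be abridged_life_table objects")
    }
    if (is.null(lt$E) || is.null(lt$d_obs)) {
      stop("tables must carry 'E' and 'd_obs' columns to be written")
    }
    data.frame(
      year = attr(lt, "year"),
      sex = attr(lt, "sex"),
      age_lower = lt$age_lower,
      age_width = lt$age_width,
      exposure = lt$E,
      deaths = lt$d_obs,
      qx = lt$q
    )
  })
  out <- do.call(rbind, rows)
  # 15 significant digits preserves the round trip well past 12
  for (col in c("exposure", "deaths", "qx")) {
    out[[col]] <- signif(out[[col]], 15)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
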