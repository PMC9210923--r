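#' Read observed and permutation p-values (or rejection counts) from
#' delimited text
#'
#' Three layouts are supported, all tab- or comma-delimited with a header
#' row:
#' * `wide` — `pvals` has one column `p`; `perms` has one column per
#'   permutation replicate, `m` rows.
#' * `long` — `pvals` as above; `perms` has columns `perm_id` and `p`,
#'   with every permutation contributing the same number of rows.
#' * `counts` — pre-reduced sufficient statistics: `pvals` has columns
#'   `threshold` and `count` (observed rejections per threshold); `perms`
#'   has `threshold`, `perm_id`, `count`. `m` must then be supplied.
#'
#' @param pvals Path to the observed-side file.
#' @param perms Path to the permutation-side file.
#' @param layout One of `"wide"`, `"long"`, `"counts"`.
#' @param m Total number of tests (required for `layout = "counts"`).
#'
#' @return For `wide`/`long`: a list with `pvals` (numeric vector) and
#'   `perms` (a [permutation_ensemble()]). For `counts`: a list with
#'   `obs_counts`, `perms` (a counts-form ensemble), `thresholds`, `m`.
#'   Feed either straight into [fdr_table()] / [fdr_table_counts()].
#' @export
read_pvalue_tables <- function(pvals, perms,
                               layout = c("wide", "long", "counts"),
                               m = NULL) {
  layout <- match.arg(layout)
  if (layout == "counts") {
    if (is.null(m)) stop("`m` is required for the counts layout", call. = FALSE)
    obs <- read_delim_auto(pvals, c("threshold", "count"))
    prm <- read_delim_auto(perms, c("threshold", "perm_id", "count"))
    obs <- dplyr::arrange(obs, dplyr::desc(.data$threshold))
    wide <- prm |>
      dplyr::arrange(dplyr::desc(.data$threshold)) |>
      tidyr::pivot_wider(names_from = "threshold", values_from = "count") |>
      dplyr::arrange(.data$perm_id)
    cmat <- as.matrix(wide[, -1, drop = FALSE])
    thr <- as.numeric(colnames(cmat))
    if (!isTRUE(all.equal(sort(thr), sort(obs$threshold)))) {
      stop("observed and permutation counts use different threshold grids",
           call. = FALSE)
    }
    ens <- permutation_ensemble(counts = cmat, m = m, thresholds = thr)
    return(list(obs_counts = obs$count, perms = ens,
                thresholds = obs$threshold, m = m))
  }
  obs <- read_delim_auto(pvals, "p")
  pv <- obs$p
  check_pvalues(pv, "observed p-values")
  if (layout == "wide") {
    prm <- read_delim_auto(perms)
    pm <- as.matrix(prm)
  } else {
    prm <- read_delim_auto(perms, c("perm_id", "p"))
    ids <- unique(prm$perm_id)
    sizes <- table(prm$perm_id)
    if (length(unique(sizes)) != 1) {
      stop("long layout: permutations have unequal numbers of rows",
           call. = FALSE)
    }
    pm <- matrix(prm$p[order(match(prm$perm_id, ids))], ncol = length(ids))
    colnames(pm) <- as.character(ids)
  }
  if (nrow(pm) != length(pv)) {
    stop("m mismatch: ", length(pv), " observed p-values vs ",
         nrow(pm), " per permutation", call. = FALSE)
  }
  if (ncol(pm) == 0) stop("empty permutation set", call. = FALSE)
  list(pvals = pv, perms = permutation_ensemble(pm))
}

read_delim_auto <- function(path, required = NULL) {
  hdr <- readLines(path, n = 1)
  delim <- if (grepl("\t", hdr)) "\t" else ","
  # parse doubles through strtod (correctly rounded), not the fast path
  x <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         progress = FALSE,
                         col_types = readr::cols(.default = "c"))
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::everything(), ~ utils::type.convert(.x, as.is = TRUE)
  ))
  if (!is.null(required) && !all(required %in% names(x))) {
    stop(basename(path), ": missing column(s) ",
         paste(setdiff(required, names(x)), collapse = ", "), call. = FALSE)
  }
  x
}

#' Write / re-read an FDR table as TSV
#'
#' Numeric columns are written with readr's shortest round-trip
#' representation, so a write/read cycle preserves every value exactly.
#' `read_fdr_table()` restores the `fdr_table` class and its `m`,
#' `n_perm`, `cl` attributes from a comment-style header line.
#'
#' @param table An `fdr_table`.
#' @param path Output path.
#'
#' @return `write_fdr_table()` returns `table` invisibly;
#'   `read_fdr_table()` returns the restored table.
#' @export
write_fdr_table <- function(table, path) {
  meta <- sprintf("# fdrscan m=%d n_perm=%d cl=%s",
                  attr(table, "m"), attr(table, "n_perm"),
                  format(attr(table, "cl"), digits = 17))
  writeLines(meta, path)
  # 17 significant digits: doubles survive the text round trip exactly
  out <- dplyr::mutate(tibble::as_tibble(table), dplyr::across(
    dplyr::where(is.double),
    ~ ifelse(is.na(.x), NA_character_, sprintf("%.17g", .x))
  ))
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE,
                   progress = FALSE)
  invisible(table)
}

#' @rdname write_fdr_table
#' @export
read_fdr_table <- function(path) {
  meta <- readLines(path, n = 1)
  x <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                       progress = FALSE,
                       col_types = readr::cols(.default = "c"))
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::everything(), ~ utils::type.convert(.x, as.is = TRUE)
  ))
  kv <- regmatches(meta, gregexpr("[a-z_]+=[^ ]+", meta))[[1]]
  vals <- stats::setNames(sub("^[a-z_]+=", "", kv), sub("=.*$", "", kv))
  if ("S" %in% names(x)) x$S <- as.integer(x$S)
  attr(x, "m") <- as.integer(vals[["m"]])
  attr(x, "n_perm") <- as.integer(vals[["n_perm"]])
  attr(x, "cl") <- as.numeric(vals[["cl"]])
  class(x) <- c("fdr_table", class(x))
  x
}
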