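# Reading and writing two-wave SIM/AUX/TRs datasets as delimited text.

#' Declare the column roles of a user dataset
#'
#' Maps dataset column names onto the roles the estimators expect. AUX can be
#' supplied as item columns (both waves, same order) and/or as ready-made sum
#' scores; missing sums are computed from the items.
#'
#' @param sim_t1,sim_t2 SIM score columns.
#' @param aux_items_t1,aux_items_t2 character vectors of AUX item columns
#'   (may be NULL when sums are given).
#' @param aux_sum_t1,aux_sum_t2 AUX sum-score columns (NULL to derive from
#'   items).
#' @param trs transition-ratings column (ordered categories, 1-based).
#' @param trs_levels number of TRs categories.
#' @param trs_cut first TRs category counted as improved.
#' @param sim_range declared SIM scale range (validation only).
#' @return object of class \code{column_mapping}.
#' @export
column_mapping <- function(sim_t1 = "sim_t1", sim_t2 = "sim_t2",
                           aux_items_t1 = NULL, aux_items_t2 = NULL,
                           aux_sum_t1 = "aux_sum_t1",
                           aux_sum_t2 = "aux_sum_t2",
                           trs = "trs7", trs_levels = 7L, trs_cut = 6L,
                           sim_range = c(0, 10)) {
  if (length(aux_items_t1) != length(aux_items_t2)) {
    stop("aux_items_t1 and aux_items_t2 must have the same length",
         call. = FALSE)
  }
  structure(list(sim_t1 = sim_t1, sim_t2 = sim_t2,
                 aux_items_t1 = aux_items_t1, aux_items_t2 = aux_items_t2,
                 aux_sum_t1 = aux_sum_t1, aux_sum_t2 = aux_sum_t2,
                 trs = trs, trs_levels = as.integer(trs_levels),
                 trs_cut = as.integer(trs_cut), sim_range = sim_range),
            class = "column_mapping")
}

#' Read and validate a two-wave dataset
#'
#' Reads delimited text (comma or tab, autodetected from the header line),
#' checks the mapped columns exist and are numeric, drops rows with missing
#' values in mapped columns (logged), and returns a table in the package's
#' canonical column layout.
#'
#' @param path file path.
#' @param mapping a \code{\link{column_mapping}}; the default matches the
#'   simulator's output.
#' @param quiet suppress the missing-data message.
#' @return data.frame with canonical columns (\code{sim_t1}, \code{sim_t2},
#'   AUX items/sums, \code{trs7}, \code{trs_improved}).
#' @export
read_mic_data <- function(path, mapping = column_mapping(), quiet = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  needed <- c(mapping$sim_t1, mapping$sim_t2, mapping$aux_items_t1,
              mapping$aux_items_t2,
              if (is.null(mapping$aux_items_t1)) mapping$aux_sum_t1,
              if (is.null(mapping$aux_items_t2)) mapping$aux_sum_t2)
  has_trs_improved <- "trs_improved" %in% names(raw) &&
    !mapping$trs %in% names(raw)
  needed <- c(needed, if (has_trs_improved) "trs_improved" else mapping$trs)
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols)) {
    stop("mapped column(s) not present: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  for (cl in needed) {
    v <- raw[[cl]]
    if (!is.numeric(v)) {
      coerced <- suppressWarnings(as.numeric(v))
      bad <- which(!is.na(v) & is.na(coerced))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s' at row %d: '%s'",
                     cl, bad[1], v[bad[1]]), call. = FALSE)
      }
      raw[[cl]] <- coerced
    }
  }
  complete <- complete.cases(raw[, needed, drop = FALSE])
  dropped <- sum(!complete)
  if (dropped > 0L && !quiet) {
    message(sprintf("read_mic_data: dropped %d row(s) with missing mapped values",
                    dropped))
  }
  raw <- raw[complete, , drop = FALSE]

  out <- data.frame(sim_t1 = raw[[mapping$sim_t1]],
                    sim_t2 = raw[[mapping$sim_t2]])
  rng <- mapping$sim_range
  if (any(out$sim_t1 < rng[1] | out$sim_t1 > rng[2] |
            out$sim_t2 < rng[1] | out$sim_t2 > rng[2])) {
    stop(sprintf("SIM scores outside the declared range [%g, %g]",
                 rng[1], rng[2]), call. = FALSE)
  }
  if (!is.null(mapping$aux_items_t1)) {
    for (k in seq_along(mapping$aux_items_t1)) {
      out[[paste0("aux", k, "_t1")]] <- raw[[mapping$aux_items_t1[k]]]
      out[[paste0("aux", k, "_t2")]] <- raw[[mapping$aux_items_t2[k]]]
    }
    out$aux_sum_t1 <- rowSums(raw[, mapping$aux_items_t1, drop = FALSE])
    out$aux_sum_t2 <- rowSums(raw[, mapping$aux_items_t2, drop = FALSE])
  }
  if (!is.null(mapping$aux_sum_t1) && mapping$aux_sum_t1 %in% names(raw)) {
    out$aux_sum_t1 <- raw[[mapping$aux_sum_t1]]
  }
  if (!is.null(mapping$aux_sum_t2) && mapping$aux_sum_t2 %in% names(raw)) {
    out$aux_sum_t2 <- raw[[mapping$aux_sum_t2]]
  }
  if (is.null(out$aux_sum_t1) || is.null(out$aux_sum_t2)) {
    stop("no AUX information: map item columns or sum-score columns",
         call. = FALSE)
  }
  if (has_trs_improved) {
    out$trs_improved <- as.integer(raw$trs_improved)
  } else {
    out$trs7 <- as.integer(raw[[mapping$trs]])
    out$trs_improved <- dichotomize_trs(out$trs7, mapping$trs_cut,
                                        mapping$trs_levels)$improved
  }
  out
}

#' Write a simulated panel (or any canonical table) to delimited text
#'
#' @param x a \code{sim_panel} or a data.frame in canonical layout.
#' @param path output path.
#' @param sep field separator (default comma).
#' @param latent also write the latent table next to \code{path} (suffix
#'   \code{_latent}); only available for \code{sim_panel} objects that kept
#'   it.
#' @return \code{path}, invisibly.
#' @export
write_mic_data <- function(x, path, sep = ",", latent = FALSE) {
  tab <- if (inherits(x, "sim_panel")) x$observed else x
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  if (latent) {
    if (!inherits(x, "sim_panel") || is.null(x$latent)) {
      stop("no latent table available to write", call. = FALSE)
    }
    lpath <- sub("(\\.[^.]+)?$", "_latent\\1", path)
    utils::write.table(x$latent, lpath, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
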