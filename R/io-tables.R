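#' Read or write a per-compound endpoint table
#'
#' The endpoint CSV schema is `id, form, binding_energy,
#' displacement_raw_pct, inhibition_pct`; blank cells are missing values.
#' `binding_energy` is Eb = -deltaG in kcal/mol, `displacement_raw_pct` the
#' raw propidium-displacement percentage, and `inhibition_pct` the graded
#' amyloid self-aggregation inhibition endpoint.
#'
#' @param path CSV path.
#' @return `read_endpoints`: a data.frame with the schema above.
#' @export
read_endpoints <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "form", "binding_energy", "displacement_raw_pct",
            "inhibition_pct")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("endpoint table missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("duplicate compound ids in endpoint table")
  for (col in need[-(1:2)]) df[[col]] <- as.numeric(df[[col]])
  df[need]
}

#' @rdname read_endpoints
#' @param endpoints Data frame with the endpoint schema.
#' @export
write_endpoints <- function(endpoints, path) {
  utils::write.csv(endpoints, path, row.names = FALSE, quote = FALSE,
                   na = "")
  invisible(path)
}

#' Serialize an overlap matrix to CSV
#'
#' Values are written as one-decimal percents (the matrix itself keeps full
#' precision); a leading `#` comment line records the matrix mode, the grid
#' spacing or sample count, and the radius table, so a heatmap file is
#' self-describing.
#'
#' @param m An [overlap_matrix()] / [cross_overlap_matrix()] result.
#' @param path Output CSV path.
#' @param digits Decimal places for serialized percents.
#' @export
write_overlap_csv <- function(m, path, digits = 1) {
  stopifnot(inherits(m, "overlap_matrix"))
  s <- m$settings
  prec <- if (s$method == "grid") sprintf("spacing=%g", s$grid_spacing)
          else sprintf("mc_samples=%d,seed=%d", s$mc_samples, s$seed)
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(sprintf("# mode=%s %s radii=%s", m$mode, prec, m$radius_table),
             con)
  vals <- formatC(round(m$values, digits), format = "f", digits = digits)
  writeLines(paste(c("id", colnames(m$values)), collapse = ","), con)
  for (i in seq_len(nrow(m$values)))
    writeLines(paste(c(rownames(m$values)[i], vals[i, ]), collapse = ","), con)
  invisible(path)
}
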