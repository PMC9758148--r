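#' Construct a LabTable
#'
#' @param values numeric matrix or data.frame (rows = records, columns =
#'   blood-test parameters); `NA` marks missing cells.
#' @return a \linkS4class{LabTable}.
#' @examples
#' lt <- LabTable(cbind(Hemoglobin = c(13.1, NA, 15.2), WBC = c(6.2, 7.1, NA)))
#' missingFraction(lt)
#' @export
LabTable <- function(values) {
  if (is.data.frame(values)) values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("LabTable", values = values)
}

#' @rdname LabTable
#' @export
setMethod("labValues", "LabTable", function(x) x@values)

#' @rdname LabTable
#' @export
setMethod("missingMask", "LabTable", function(x) is.na(x@values))

#' @rdname LabTable
#' @export
setMethod("missingFraction", "LabTable",
          function(x) colMeans(is.na(x@values)))

setMethod("dim", "LabTable", function(x) dim(x@values))

setMethod("show", "LabTable", function(object) {
  d <- dim(object@values)
  mf <- mean(is.na(object@values))
  cat(sprintf("LabTable: %d records x %d variables (%.1f%% missing)\n",
              d[1], d[2], 100 * mf))
  cat("variables:", paste(utils::head(colnames(object@values), 8), collapse = ", "),
      if (d[2] > 8) "...", "\n")
})

#' Read / write a LabTable as CSV (blank cell = missing)
#'
#' @param file path to a CSV file whose header row names the variables.
#' @return [readLabTable()] returns a \linkS4class{LabTable}.
#' @export
readLabTable <- function(file) {
  df <- utils::read.csv(file, check.names = FALSE)
  LabTable(df)
}

#' @rdname readLabTable
#' @param x a \linkS4class{LabTable}.
#' @export
writeLabTable <- function(x, file) {
  utils::write.csv(as.data.frame(labValues(x)), file, row.names = FALSE,
                   na = "")
  invisible(file)
}

# replace a column's values, keeping everything else untouched
setLabColumn <- function(x, variable, values) {
  v <- x@values
  v[, variable] <- values
  new("LabTable", values = v)
}
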