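#' Read a binary-outcome dataset from CSV
#'
#' Reads a comma-separated file with header, checks the outcome column is
#' binary, drops incomplete rows among the used columns (with a message),
#' and expands categorical covariates to reference-coded indicator columns
#' (reference = first level encountered, overridable via `references`).
#'
#' @param path Path to the CSV file.
#' @param outcome Name of the 0/1 outcome column.
#' @param structural Character vector of column names for the exposure
#'   (structural) part, or `NULL`.
#' @param occurrence Character vector of column names for the occurrence
#'   part, or `NULL`.
#' @param references Optional named character vector mapping a categorical
#'   column to its reference level.
#' @return A list with `y` (numeric 0/1 vector), `X` and `Z` (numeric
#'   design matrices without intercept; 0 columns when the part has no
#'   covariates), and `manifest` describing the column coding and the
#'   number of dropped rows.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' write.csv(data.frame(y = c(0, 1, 1, 0), g = c("a", "b", "c", "a")),
#'           f, row.names = FALSE)
#' str(read_zib_data(f, outcome = "y", structural = "g"))
#' @export
read_zib_data <- function(path, outcome, structural = NULL,
                          occurrence = NULL, references = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  used <- unique(c(outcome, structural, occurrence))
  missing_cols <- setdiff(used, names(df))
  if (length(missing_cols))
    stop("unknown column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df <- df[used]
  complete <- stats::complete.cases(df)
  dropped <- sum(!complete)
  if (dropped > 0) {
    message(sprintf("dropped %d row(s) with missing values", dropped))
    df <- df[complete, , drop = FALSE]
  }
  y <- df[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  if (!is.numeric(y) || any(y != 0 & y != 1))
    stop(sprintf("outcome column '%s' is not coercible to 0/1", outcome),
         call. = FALSE)

  coding <- list()
  expand <- function(cols) {
    if (is.null(cols) || !length(cols))
      return(matrix(numeric(0), nrow(df), 0))
    blocks <- lapply(cols, function(cn) {
      v <- df[[cn]]
      if (is.numeric(v)) {
        coding[[cn]] <<- list(type = "numeric")
        return(matrix(v, ncol = 1, dimnames = list(NULL, cn)))
      }
      lev <- unique(as.character(v))        # reference = first encountered
      ref <- if (!is.null(references) && cn %in% names(references))
        references[[cn]] else lev[1]
      lev <- c(ref, setdiff(lev, ref))
      f <- factor(as.character(v), levels = lev)
      mm <- stats::model.matrix(~ f)[, -1, drop = FALSE]
      colnames(mm) <- paste0(cn, lev[-1])
      coding[[cn]] <<- list(type = "categorical", levels = lev,
                            reference = ref)
      mm
    })
    do.call(cbind, blocks)
  }
  X <- expand(structural)
  Z <- expand(occurrence)
  list(y = y, X = X, Z = Z,
       manifest = list(outcome = outcome, coding = coding,
                       dropped_rows = dropped, n = length(y)))
}
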