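#' Environmental grid container
#'
#' A cell-indexed stack of environmental variables on a regular grid of unit
#' cells. Cells are stored row-major (cell 1 is row 1, column 1). Variables
#' are tagged as `"static"` (topography, soil) or `"climate"` (the layers
#' that change under future scenarios). A cell is valid when every variable
#' is non-missing; soil gaps can be filled with [idw_fill()].
#'
#' @param values numeric matrix, cells x variables, with column names.
#' @param dims integer vector `c(rows, cols)`; `prod(dims)` must equal
#'   `nrow(values)`.
#' @param var_types character vector (`"static"` or `"climate"`) per column.
#' @param epoch `"current"` or `"future"`.
#' @param scenario,slice optional tags carried through projections.
#' @return An object of class `env_grid`.
#' @export
env_grid <- function(values, dims, var_types,
                     epoch = "current", scenario = NULL, slice = NULL) {
  values <- as.matrix(values)
  dims <- as.integer(dims)
  if (length(dims) != 2L || any(dims <= 0L)) {
    stop("`dims` must be two positive integers", call. = FALSE)
  }
  if (prod(dims) != nrow(values)) {
    stop("nrow(values) must equal prod(dims)", call. = FALSE)
  }
  if (is.null(colnames(values))) stop("`values` needs column names", call. = FALSE)
  var_types <- match.arg(var_types, c("static", "climate"), several.ok = TRUE)
  if (length(var_types) != ncol(values)) {
    stop("one var_type per variable required", call. = FALSE)
  }
  structure(
    list(values = values, dims = dims,
         var_types = stats::setNames(var_types, colnames(values)),
         epoch = epoch, scenario = scenario, slice = slice),
    class = "env_grid"
  )
}

#' @export
print.env_grid <- function(x, ...) {
  cat(sprintf("env_grid: %d x %d cells (%d valid), %d variables [%s epoch]\n",
              x$dims[1], x$dims[2], sum(valid_cells(x)), ncol(x$values), x$epoch))
  cat("  variables:", paste(colnames(x$values), collapse = ", "), "\n")
  invisible(x)
}

#' Logical vector of cells with no missing variable values
#' @param env an [env_grid()].
#' @return logical vector, one element per cell.
#' @export
valid_cells <- function(env) {
  stopifnot(inherits(env, "env_grid"))
  stats::complete.cases(env$values)
}

#' Row/column coordinates of each cell (unit squares, row-major order)
#' @param env an [env_grid()].
#' @return data.frame with `cell_id`, `row`, `col`.
#' @export
cell_coords <- function(env) {
  stopifnot(inherits(env, "env_grid"))
  nr <- env$dims[1]; nc <- env$dims[2]
  data.frame(cell_id = seq_len(nr * nc),
             row = rep(seq_len(nr), each = nc),
             col = rep(seq_len(nc), times = nr))
}

#' Write an environmental grid as a long-format table
#'
#' One row per cell x variable: `cell_id,row,col,variable,value`.
#' @param env an [env_grid()].
#' @param path file to write (CSV).
#' @return `path`, invisibly.
#' @export
write_env_grid <- function(env, path) {
  co <- cell_coords(env)
  long <- do.call(rbind, lapply(colnames(env$values), function(v) {
    data.frame(cell_id = co$cell_id, row = co$row, col = co$col,
               variable = v, value = env$values[, v])
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read an environmental grid from a long-format table
#' @param path CSV written by [write_env_grid()].
#' @param var_types named character vector of variable types; defaults to
#'   `"climate"` for every variable.
#' @inheritParams env_grid
#' @return An [env_grid()].
#' @export
read_env_grid <- function(path, var_types = NULL, epoch = "current") {
  long <- utils::read.csv(path)
  vars <- unique(long$variable)
  dims <- c(max(long$row), max(long$col))
  values <- sapply(vars, function(v) {
    sub <- long[long$variable == v, ]
    sub$value[order(sub$cell_id)]
  })
  colnames(values) <- vars
  if (is.null(var_types)) var_types <- stats::setNames(rep("climate", length(vars)), vars)
  env_grid(values, dims, var_types[vars], epoch = epoch)
}
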