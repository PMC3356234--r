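# System state: all model fields on one radial grid at one instant.
#
# Field order is fixed and shared by the state matrix, the integrator's
# packed vector, and trajectory arrays. The chemicals (R, M, F, P) diffuse;
# the cell-state densities (C, S_T, S_A, D_N), the matrix density U and the
# apoptosis ledger D_A do not (chondrocytes are immobile in the matrix).

CHONDRO_FIELDS <- c("R", "M", "F", "P", "C", "S_T", "S_A", "D_N", "U", "D_A")
CHONDRO_CHEMICALS <- c("R", "M", "F", "P")

#' Construct a system state
#'
#' Bundles the nine dynamical fields (four cytokine concentrations, four
#' cell-state densities, matrix density) plus the cumulative apoptosis
#' ledger `D_A` on a radial grid at one time. `D_A` is bookkeeping only: it
#' accumulates apoptotic deaths so that total cells are conserved across
#' state changes, but it feeds back into nothing.
#'
#' @param grid A [radial_grid()].
#' @param t Time in hours.
#' @param ... Named fields among `R`, `M`, `F`, `P`, `C`, `S_T`, `S_A`,
#'   `D_N`, `U`, `D_A`; each a scalar (recycled) or a vector of length
#'   `grid$n_nodes`. Omitted fields are zero.
#' @return An object of class `chondro_state`: list with `t`, `grid`, and
#'   `fields` (an `n_nodes` x 10 matrix with named columns).
#' @export
system_state <- function(grid, t = 0, ...) {
  stopifnot(inherits(grid, "radial_grid"))
  n <- grid$n_nodes
  fields <- matrix(0, n, length(CHONDRO_FIELDS),
                   dimnames = list(NULL, CHONDRO_FIELDS))
  dots <- list(...)
  unknown <- setdiff(names(dots), CHONDRO_FIELDS)
  if (length(unknown) > 0) {
    stop("unknown field(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  for (nm in names(dots)) {
    v <- dots[[nm]]
    if (!length(v) %in% c(1, n)) {
      stop("field `", nm, "` must have length 1 or ", n, call. = FALSE)
    }
    fields[, nm] <- v
  }
  if (any(fields < 0)) {
    stop("all state fields must be non-negative", call. = FALSE)
  }
  structure(list(t = t, grid = grid, fields = fields), class = "chondro_state")
}

#' @export
print.chondro_state <- function(x, ...) {
  cat("<chondro_state> t =", x$t, "h on", x$grid$n_nodes, "nodes\n")
  tot <- colSums(x$fields * x$grid$cell_areas)
  cat("  area integrals:",
      paste(colnames(x$fields), format(tot, digits = 4), sep = "=",
            collapse = " "), "\n")
  invisible(x)
}

# pack/unpack between the n x 10 field matrix and the integrator's vector
.pack_state <- function(fields) as.vector(fields)
.unpack_state <- function(y, n) {
  matrix(y, n, length(CHONDRO_FIELDS), dimnames = list(NULL, CHONDRO_FIELDS))
}

#' Spatially integrate a field over the domain
#'
#' @param state A `chondro_state`.
#' @param field Field name (one of the ten model fields).
#' @return The area integral of the field (e.g. total cells for a density).
#' @export
integrate_field <- function(state, field) {
  stopifnot(inherits(state, "chondro_state"))
  field <- match.arg(field, CHONDRO_FIELDS)
  sum(state$fields[, field] * state$grid$cell_areas)
}
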