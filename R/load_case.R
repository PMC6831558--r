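# Muscle-force loading and constraint scheme for the simulated unilateral
# chewing experiments.
#
# Anatomical frame (documented convention, used throughout the package):
#   X = superoinferior (up positive), Y = anteroposterior (anterior
#   positive), Z = mediolateral. Sagittal shear is then the XY tensor
#   component, frontal XZ and transverse YZ.

#' Total force vector of one muscle
#'
#' Magnitude is physiological cross-sectional area times the muscle
#' specific tension (default 30 N/cm^2) times the normalised EMG activation
#' scale; direction is the unit vector from the centroid of the mandibular
#' insertion node set toward the cranial origin point.
#'
#' @param muscle one-row data.frame (or list) with fields `pcsa_cm2`,
#'   `emg_scale`, `origin_x`, `origin_y`, `origin_z`, `insertion_set`.
#' @param mesh a `tet_mesh` providing the insertion node set.
#' @param specific_tension muscle specific tension, N/cm^2.
#' @return list with `force` (N triple), `magnitude` (N), `direction`
#'   (unit triple), `centroid` (insertion centroid, mm).
#' @export
muscle_force <- function(muscle, mesh, specific_tension = 30) {
  pcsa <- as.numeric(muscle$pcsa_cm2)
  emg <- as.numeric(muscle$emg_scale)
  if (!is.finite(pcsa) || pcsa <= 0) stop("pcsa must be > 0")
  if (!is.finite(emg) || emg < 0 || emg > 1)
    stop("emg_scale must be in [0, 1]")
  set_name <- as.character(muscle$insertion_set)
  nodes <- mesh$node_sets[[set_name]]
  if (is.null(nodes) || length(nodes) == 0)
    stop("missing or empty insertion node set '", set_name, "'")
  centroid <- colMeans(mesh$nodes[nodes, , drop = FALSE])
  origin <- c(as.numeric(muscle$origin_x), as.numeric(muscle$origin_y),
              as.numeric(muscle$origin_z))
  d <- origin - centroid
  len <- sqrt(sum(d^2))
  if (len < 1e-12)
    stop("muscle '", muscle$name,
         "': origin coincides with insertion centroid (zero direction)")
  dir <- d / len
  mag <- pcsa * specific_tension * emg
  list(force = mag * dir, magnitude = mag, direction = dir,
       centroid = centroid)
}

#' Distribute a total force equally over insertion nodes
#'
#' @param total N triple.
#' @param nodes integer vector of node ids (non-empty).
#' @return matrix `length(nodes) x 3`; rows sum to `total`.
#' @export
distribute_force <- function(total, nodes) {
  if (length(nodes) == 0) stop("empty insertion node list")
  matrix(rep(as.numeric(total) / length(nodes), each = length(nodes)),
         ncol = 3L)
}

#' Read / write muscle definition tables
#'
#' CSV columns: `name`, `side` (`working`/`balancing`), `pcsa_cm2`,
#' `emg_scale`, `origin_x`, `origin_y`, `origin_z`, `insertion_set`.
#'
#' @param path CSV file.
#' @return data.frame of muscle definitions.
#' @export
read_muscles <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "side", "pcsa_cm2", "emg_scale",
            "origin_x", "origin_y", "origin_z", "insertion_set")
  miss <- setdiff(need, names(m))
  if (length(miss)) stop("muscle table missing column(s): ",
                         paste(miss, collapse = ", "))
  m
}

#' @rdname read_muscles
#' @param muscles muscle data.frame.
#' @export
write_muscles <- function(muscles, path) {
  utils::write.csv(muscles, path, row.names = FALSE)
  invisible(path)
}

.constraint_spec <- function(set_name, nodes, axes) {
  axes <- sort(unique(match(axes, c("X", "Y", "Z"))))
  if (length(axes) == 0 || anyNA(axes)) stop("fixed_axes must be subset of X,Y,Z")
  if (length(nodes) == 0) stop("constraint node set '", set_name, "' is empty")
  list(set = set_name, nodes = as.integer(nodes), axes = as.integer(axes))
}

#' Build the load case for a chewing simulation
#'
#' Assembles nodal muscle forces (equal split over each muscle's insertion
#' node set) and the constraint scheme:
#' \itemize{
#'   \item `chewing` (default): occlusal surfaces of the working-side bite
#'     teeth fixed against translation in all directions (the bite
#'     constraint from which bite force emerges); the working-side condyle
#'     node fixed in all directions; the balancing-side condyle node fixed
#'     superoinferiorly (X) and anteroposteriorly (Y) but free to translate
#'     mediolaterally (Z), which permits lateral transverse bending.
#'   \item `overconstrained`: both condyle nodes fixed in all directions
#'     (the sensitivity scenario for condylar boundary conditions).
#'   \item `clenching`: chewing constraints, but each muscle's
#'     `emg_scale` replaced from `emg_table` (columns `name`, `side`,
#'     `emg_scale`) to emulate a different activation regime.
#' }
#'
#' Required node sets on the mesh: `bite_occlusal`, `condyle_working`,
#' `condyle_balancing`, plus one insertion set per muscle.
#'
#' @param mesh a `tet_mesh`.
#' @param muscles muscle definition data.frame (see [read_muscles()]).
#' @param scenario `"chewing"`, `"overconstrained"` or `"clenching"`.
#' @param emg_table replacement activation table for `"clenching"`.
#' @param specific_tension muscle specific tension, N/cm^2.
#' @return an object of class `load_case`: `forces` (n x 3 N), `constraints`
#'   (list of specs), `scenario`, `muscle_totals` (per-muscle force triples).
#' @export
build_chewing_case <- function(mesh, muscles,
                               scenario = c("chewing", "overconstrained",
                                            "clenching"),
                               emg_table = NULL, specific_tension = 30) {
  scenario <- match.arg(scenario)
  for (s in c("bite_occlusal", "condyle_working", "condyle_balancing"))
    if (is.null(mesh$node_sets[[s]]))
      stop("mesh is missing required node set '", s, "'")
  if (scenario == "clenching") {
    if (is.null(emg_table))
      stop("scenario 'clenching' requires emg_table (name, side, emg_scale)")
    key <- paste(muscles$name, muscles$side)
    tkey <- paste(emg_table$name, emg_table$side)
    idx <- match(key, tkey)
    if (anyNA(idx))
      stop("emg_table missing entries for: ",
           paste(key[is.na(idx)], collapse = ", "))
    muscles$emg_scale <- emg_table$emg_scale[idx]
  }
  n <- nrow(mesh$nodes)
  forces <- matrix(0, n, 3L)
  totals <- matrix(0, nrow(muscles), 3L,
                   dimnames = list(paste(muscles$name, muscles$side), NULL))
  for (i in seq_len(nrow(muscles))) {
    mf <- muscle_force(muscles[i, ], mesh, specific_tension)
    ins <- mesh$node_sets[[as.character(muscles$insertion_set[i])]]
    forces[ins, ] <- forces[ins, , drop = FALSE] + distribute_force(mf$force, ins)
    totals[i, ] <- mf$force
  }
  constraints <- list(
    .constraint_spec("bite_occlusal", mesh$node_sets$bite_occlusal,
                     c("X", "Y", "Z")),
    .constraint_spec("condyle_working", mesh$node_sets$condyle_working,
                     c("X", "Y", "Z")),
    if (scenario == "overconstrained")
      .constraint_spec("condyle_balancing", mesh$node_sets$condyle_balancing,
                       c("X", "Y", "Z"))
    else
      .constraint_spec("condyle_balancing", mesh$node_sets$condyle_balancing,
                       c("X", "Y"))
  )
  lc <- structure(list(forces = forces, constraints = constraints,
                       scenario = scenario, muscle_totals = totals),
                  class = "load_case")
  .zero_fixed_loads(lc)
}

# warn + zero force components applied along fully-fixed nodes' fixed axes
.zero_fixed_loads <- function(lc) {
  for (cs in lc$constraints) {
    if (length(cs$axes) == 3L) {
      sub <- lc$forces[cs$nodes, , drop = FALSE]
      if (any(sub != 0)) {
        warning("nonzero load on fully fixed node set '", cs$set,
                "'; zeroing the fixed components")
        lc$forces[cs$nodes, ] <- 0
      }
    }
  }
  lc
}

#' @export
print.load_case <- function(x, ...) {
  cat("load_case (", x$scenario, "): ", sum(rowSums(x$forces != 0) > 0),
      " loaded nodes, net force [",
      paste(sprintf("%.2f", colSums(x$forces)), collapse = ", "), "] N\n",
      sep = "")
  for (cs in x$constraints)
    cat("  constraint ", cs$set, ": ", length(cs$nodes), " node(s), fixed ",
        paste(c("X", "Y", "Z")[cs$axes], collapse = ""), "\n", sep = "")
  invisible(x)
}
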