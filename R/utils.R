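# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ip <- function(class, fmt, ...) {
  msg <- sprintf(fmt, ...)
  stop(structure(class = c(class, "ionpath_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# squared distances between rows of a (m x 3) and rows of b (n x 3); m x n
dist2_xyz <- function(a, b) {
  outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
}

# clearance of query points against a set of atoms:
# min over atoms of (|p - a_i| - vdw_i); compiled kernel
clearance_points <- function(points, atom_xyz, atom_vdw) {
  clearance_cpp(as.matrix(points), as.matrix(atom_xyz),
                as.numeric(atom_vdw))
}

# minimum-image displacement components for an orthorhombic box
min_image <- function(d, box) {
  if (is.null(box)) return(d)
  for (k in 1:3) d[, k] <- d[, k] - box[k] * round(d[, k] / box[k])
  d
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
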