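# Internal validation helpers shared across modules.

stop_if <- function(cond, msg, class = "mdgraph_error") {
  if (isTRUE(cond)) {
    stop(structure(class = c(class, "error", "condition"),
                   list(message = msg, call = sys.call(-1))))
  }
  invisible(NULL)
}

check_adjacency <- function(A, what = "adjacency matrix") {
  stop_if(!is.matrix(A) || !is.numeric(A), sprintf("%s must be a numeric matrix", what),
          "mdgraph_shape_error")
  stop_if(nrow(A) != ncol(A), sprintf("%s must be square", what), "mdgraph_shape_error")
  stop_if(any(!is.finite(A)), sprintf("%s contains non-finite values", what))
  invisible(A)
}

check_binary_adjacency <- function(A, what = "adjacency matrix") {
  check_adjacency(A, what)
  stop_if(!all(A %in% c(0, 1)), sprintf("%s must be binary", what))
  stop_if(any(diag(A) != 0), sprintf("%s must have a zero diagonal", what))
  stop_if(!isTRUE(all.equal(A, t(A))), sprintf("%s must be symmetric", what))
  invisible(A)
}

check_finite_matrix <- function(X, what = "matrix") {
  stop_if(!is.matrix(X) || !is.numeric(X), sprintf("%s must be a numeric matrix", what),
          "mdgraph_shape_error")
  stop_if(any(!is.finite(X)), sprintf("%s contains non-finite values", what))
  invisible(X)
}

# One positive-part ReLU used everywhere.
relu <- function(x) pmax(x, 0)

sigmoid <- function(x) 1 / (1 + exp(-x))

# Numerically stable softmax over a vector.
softmax_vec <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}
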