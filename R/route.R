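# Route container: a time-ordered sequence of agent poses, shared by
# training and test phases.

new_ant_route <- function(poses, kind = c("training", "test"), start, goal,
                          nominal_length, termination = NA_character_) {
  kind <- match.arg(kind)
  structure(
    list(poses = poses, kind = kind, start = start, goal = goal,
         nominal_length = nominal_length, termination = termination),
    class = "ant_route"
  )
}

#' @export
print.ant_route <- function(x, ...) {
  cat(sprintf(
    "<ant_route> %s route: %d poses, path length %.1f m (nominal %.1f m)%s\n",
    x$kind, nrow(x$poses), route_path_length(x), x$nominal_length,
    if (is.na(x$termination)) "" else paste0(", terminated: ", x$termination)
  ))
  invisible(x)
}

route_path_length <- function(route) {
  p <- route$poses
  if (nrow(p) < 2) return(0)
  sum(sqrt(diff(p$x)^2 + diff(p$y)^2))
}

# positions as an n x 2 matrix from routes, recap results, data frames or
# bare matrices
route_positions <- function(x) {
  if (inherits(x, "ant_recap")) x <- x$route
  if (inherits(x, "ant_route")) {
    return(cbind(x$poses$x, x$poses$y))
  }
  if (is.data.frame(x)) return(cbind(x$x, x$y))
  if (is.matrix(x) && ncol(x) == 2) return(x)
  stop("cannot extract positions from this object", call. = FALSE)
}
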