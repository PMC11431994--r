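# Independent geometry oracles backed by scipy.spatial (called through the
# system python), kept separate from the package's own hull implementation.

run_python <- function(code) {
  out <- suppressWarnings(system2("python", "-", stdout = TRUE,
                                  stderr = TRUE, input = code))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0)
    stop("python oracle failed:\n", paste(out, collapse = "\n"))
  out
}

write_points_csv <- function(points) {
  f <- tempfile(fileext = ".csv")
  utils::write.table(points, f, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  f
}

# Monte-Carlo hull volume: uniform draws in the bounding box, membership via
# the hull's facet inequalities (scipy's qhull, not ours)
mc_hull_volume <- function(points, n_draws = 1e6, seed = 1) {
  f <- write_points_csv(points)
  on.exit(unlink(f))
  code <- sprintf('
import numpy as np
from scipy.spatial import ConvexHull
pts = np.loadtxt(%s, delimiter=",")
rng = np.random.default_rng(%d)
lo, hi = pts.min(0), pts.max(0)
box = float(np.prod(hi - lo))
hull = ConvexHull(pts)
A = hull.equations[:, :-1]
b = -hull.equations[:, -1]
n = %d
inside = 0
step = 200000
for start in range(0, n, step):
    k = min(step, n - start)
    x = rng.uniform(lo, hi, size=(k, pts.shape[1]))
    inside += int(((x @ A.T) <= b + 1e-12).all(axis=1).sum())
print(repr(inside / n * box))
', deparse(f), as.integer(seed), as.integer(n_draws))
  as.numeric(tail(run_python(code), 1))
}

# independent enumeration oracle for the Mann-Whitney test: U computed by
# direct pairwise comparison for every labeling of the pooled values
mw_enumeration_oracle <- function(x, y) {
  pool <- c(x, y)
  n <- length(x); m <- length(y); N <- n + m
  u_of <- function(xs, ys) sum(outer(xs, ys, ">") + 0.5 * outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  centre <- n * m / 2
  subsets <- combn(N, n)
  us <- apply(subsets, 2, function(ix) u_of(pool[ix], pool[-ix]))
  mean(abs(us - centre) >= abs(u_obs - centre) - 1e-9)
}

# exact qhull volume, for tighter cross-checks
scipy_hull_volume <- function(points) {
  f <- write_points_csv(points)
  on.exit(unlink(f))
  code <- sprintf('
import numpy as np
from scipy.spatial import ConvexHull
pts = np.loadtxt(%s, delimiter=",")
print(repr(float(ConvexHull(pts).volume)))
', deparse(f))
  as.numeric(tail(run_python(code), 1))
}
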