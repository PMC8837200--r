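# supersampling oracle for grid coverage: visited cells from points placed
# every `step` cm along each segment (plus the vertices themselves)
supersample_cells <- function(traj, arena, step = 0.01) {
  cs <- arena$cell_size
  nx <- ceiling(arena$width / cs)
  ny <- ceiling(arena$height / cs)
  code <- function(x, y) {
    pmin(floor(x / cs), nx - 1) * ny + pmin(floor(y / cs), ny - 1)
  }
  cells <- code(traj$x, traj$y)
  for (i in seq_len(nrow(traj) - 1)) {
    d <- sqrt((traj$x[i + 1] - traj$x[i])^2 + (traj$y[i + 1] - traj$y[i])^2)
    if (d == 0) next
    f <- seq(0, 1, length.out = max(2, ceiling(d / step) + 1))
    cells <- c(cells, code(traj$x[i] + f * (traj$x[i + 1] - traj$x[i]),
                           traj$y[i] + f * (traj$y[i + 1] - traj$y[i])))
  }
  sort(unique(cells))
}
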