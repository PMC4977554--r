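# Independent oracles used to freeze expected values.

# Hull-deficit oracle independent of the package's quickhull: voxel-centre
# membership in the convex hull computed by Qhull (scipy.spatial.Delaunay)
# through the system python. Returns the deficit percent.
oracle_hull_deficit <- function(mask) {
  py <- Sys.which("python")
  if (py == "") py <- Sys.which("python3")
  if (py == "") stop("no python available for the Qhull oracle")
  fg <- mask$data > 0
  pts <- which(fg, arr.ind = TRUE) - 1
  lo <- apply(pts, 2, min)
  hi <- apply(pts, 2, max)
  grid <- as.matrix(expand.grid(lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]))
  ptf <- tempfile(fileext = ".csv")
  grf <- tempfile(fileext = ".csv")
  outf <- tempfile(fileext = ".txt")
  utils::write.table(pts, ptf, row.names = FALSE, col.names = FALSE, sep = ",")
  utils::write.table(grid, grf, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- sprintf(paste0(
    "import numpy as np\n",
    "from scipy.spatial import Delaunay\n",
    "pts = np.loadtxt(%s, delimiter=',')\n",
    "grid = np.loadtxt(%s, delimiter=',')\n",
    "hull = Delaunay(pts)\n",
    "inside = hull.find_simplex(grid) >= 0\n",
    "np.savetxt(%s, inside.astype(int), fmt='%%d')\n"),
    shQuote(ptf), shQuote(grf), shQuote(outf))
  res <- system2(py, c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  if (!file.exists(outf)) stop("Qhull oracle failed: ", paste(res, collapse = " "))
  inside <- as.integer(readLines(outf))
  v_hull <- sum(inside)
  v_mask <- sum(fg)
  100 * (v_hull - v_mask) / v_hull
}

# brute-force in-nucleus Pearson correlation (plain formula, no cor())
oracle_pearson <- function(a, b) {
  am <- a - mean(a)
  bm <- b - mean(b)
  sum(am * bm) / sqrt(sum(am^2) * sum(bm^2))
}
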