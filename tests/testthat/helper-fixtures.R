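# shared fixtures: all built in code, seeded

# 2-channel closed-form instance: SAR(phi) = 2 + cos(phi2 - phi1 + pi/2),
# worst case 3.0 at phi2 - phi1 = -pi/2
q_closed_form <- function() {
  q_matrix(matrix(c(1, -0.5i, 0.5i, 1), 2, 2))
}

# rank-1 instance Q = v v^H (Q[n,m] = v_n conj(v_m)) with v = (1, i):
# eigenvector v, worst case for s = (1, 2) is (1*1 + 2*1)^2 = 9, lambda_max = 2
q_rank1 <- function() {
  v <- c(1, 1i)
  q_matrix(outer(v, Conj(v)))
}

random_hermitian_psd <- function(nc, rank = 3, seed = 1) {
  random_q_ensemble(1, nc = nc, rank = rank, seed = seed)$matrices[[1]]
}

# small homogeneous grid + random complex fields (not physical; for qmodel)
random_field_set <- function(shape = c(7, 7, 7), nc = 4, seed = 1,
                             voxel_size = 5e-3) {
  grid <- tissue_grid(shape, voxel_size, sigma = 0.5, rho = 1000)
  set.seed(seed)
  dims <- c(nc, shape)
  mk <- function() array(complex(real = rnorm(prod(dims)),
                                 imaginary = rnorm(prod(dims))), dims)
  channel_field_set(grid, mk(), mk(), mk())
}

simplex_amplitudes <- function(nc, seed) {
  set.seed(seed)
  p <- rexp(nc)
  sqrt(p / sum(p))
}

# MATLAB v7.3-style fixture files written by an independent producer (h5py);
# returns paths of an array-variable file and a cell-array file holding the
# same matrices, plus an R copy of the matrices
write_matlab_fixture_pair <- function(dir) {
  script <- '
import h5py, numpy as np, sys
out_arr, out_cell = sys.argv[1], sys.argv[2]
rng = np.random.default_rng(20)
def randq(nc, rank=3):
    q = np.zeros((nc, nc), complex)
    for _ in range(rank):
        v = (rng.standard_normal(nc) + 1j*rng.standard_normal(nc))/np.sqrt(2)
        q += np.outer(v.conj(), v)
    return (q + q.conj().T)/2
mats = [randq(4) for _ in range(5)]
dt = np.dtype([("real","<f8"),("imag","<f8")])
def comp(x):
    m = np.zeros(x.shape, dtype=dt); m["real"]=x.real; m["imag"]=x.imag; return m
# MATLAB stores arrays with reversed axis order; transpose each slice
arr = np.stack([m.T for m in mats], axis=0)
with h5py.File(out_arr, "w") as f:
    d = f.create_dataset("Q10g", data=comp(arr))
    d.attrs["MATLAB_class"] = np.bytes_("double")
with h5py.File(out_cell, "w") as f:
    refs = f.create_group("#refs#")
    rs = []
    for k, x in enumerate(mats):
        d = refs.create_dataset("m%d" % k, data=comp(x.T))
        d.attrs["MATLAB_class"] = np.bytes_("double")
        rs.append(d.ref)
    cd = f.create_dataset("VOPs",
                          data=np.array(rs, dtype=h5py.ref_dtype).reshape(-1, 1))
    cd.attrs["MATLAB_class"] = np.bytes_("cell")
np.savetxt(sys.argv[3], np.column_stack([m.flatten(order="F").real for m in mats]))
np.savetxt(sys.argv[4], np.column_stack([m.flatten(order="F").imag for m in mats]))
'
  f_arr <- file.path(dir, "ml_arr.mat")
  f_cell <- file.path(dir, "ml_cell.mat")
  f_re <- file.path(dir, "ref_re.txt")
  f_im <- file.path(dir, "ref_im.txt")
  sf <- file.path(dir, "make_fixture.py")
  writeLines(script, sf)
  status <- system2("python", c(sf, f_arr, f_cell, f_re, f_im),
                    stdout = FALSE, stderr = FALSE)
  stopifnot(status == 0)
  re <- as.matrix(read.table(f_re))
  im <- as.matrix(read.table(f_im))
  mats <- lapply(seq_len(ncol(re)),
                 function(k) matrix(complex(real = re[, k],
                                            imaginary = im[, k]), 4, 4))
  list(arr = f_arr, cell = f_cell, mats = mats)
}
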