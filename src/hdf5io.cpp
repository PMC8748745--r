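// Minimal HDF5 bindings: one 3D numeric dataset per key, read as double,
// written as IEEE float64 (intensities) or uint32 (labels). Row-major HDF5
// dims are returned as-is; the R side handles the (Z,Y,X) axis convention.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>

using namespace Rcpp;

// report failures through R conditions only, not the HDF5 stderr trace
static void h5_quiet() {
  static bool done = false;
  if (!done) { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); done = true; }
}

// [[Rcpp::export]]
List cpp_h5_read(std::string path, std::string key) {
  h5_quiet();
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  hid_t dset = H5Dopen2(file, key.c_str(), H5P_DEFAULT);
  if (dset < 0) { H5Fclose(file); stop("no dataset '%s' in '%s'", key.c_str(), path.c_str()); }
  hid_t space = H5Dget_space(dset);
  int nd = H5Sget_simple_extent_ndims(space);
  if (nd != 3) {
    H5Sclose(space); H5Dclose(dset); H5Fclose(file);
    stop("dataset '%s' is %d-dimensional; expected 3D (non-3D data)", key.c_str(), nd);
  }
  hsize_t dims[3];
  H5Sget_simple_extent_dims(space, dims, NULL);
  R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  NumericVector buf(n);
  herr_t st = H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                      REAL(buf));
  H5Sclose(space); H5Dclose(dset); H5Fclose(file);
  if (st < 0) stop("failed reading dataset '%s'", key.c_str());
  IntegerVector d(3);
  d[0] = (int)dims[0]; d[1] = (int)dims[1]; d[2] = (int)dims[2];
  return List::create(_["data"] = buf, _["dims"] = d);
}

// [[Rcpp::export]]
void cpp_h5_write(std::string path, std::string key, NumericVector data,
                  IntegerVector dims, bool as_uint32, bool overwrite_file) {
  h5_quiet();
  hid_t file;
  if (overwrite_file)
    file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  else {
    file = H5Fopen(path.c_str(), H5F_ACC_RDWR, H5P_DEFAULT);
    if (file < 0)
      file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  }
  if (file < 0) stop("cannot create HDF5 file '%s' (unwritable path)", path.c_str());
  hsize_t d[3] = { (hsize_t)dims[0], (hsize_t)dims[1], (hsize_t)dims[2] };
  hid_t space = H5Screate_simple(3, d, NULL);
  hid_t ftype = as_uint32 ? H5T_STD_U32LE : H5T_IEEE_F64LE;
  if (H5Lexists(file, key.c_str(), H5P_DEFAULT) > 0)
    H5Ldelete(file, key.c_str(), H5P_DEFAULT);
  hid_t dset = H5Dcreate2(file, key.c_str(), ftype, space, H5P_DEFAULT,
                          H5P_DEFAULT, H5P_DEFAULT);
  if (dset < 0) { H5Sclose(space); H5Fclose(file); stop("cannot create dataset '%s'", key.c_str()); }
  herr_t st = H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                       REAL(data));
  H5Dclose(dset); H5Sclose(space); H5Fclose(file);
  if (st < 0) stop("failed writing dataset '%s'", key.c_str());
}
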