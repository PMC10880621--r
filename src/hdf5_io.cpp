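// Minimal HDF5 backend for the hyperspectral cube container.
//
// On-disk layout (format_version 1):
//   root attributes : format_version (int), pixel_size_um (double),
//                     modality (string)
//   datasets        : /wavenumbers_cm1 (1-D float64)
//                     /absorbance      (3-D float64, rows x cols x n_wn)
//   group           : /provenance with string attributes (one per entry)
//
// The R wrappers handle the column-major <-> row-major permutation; the
// numeric buffer crossing this boundary is laid out in HDF5 (C) order,
// i.e. wavenumber index fastest.

#include <Rcpp.h>
#include <hdf5.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

namespace {

struct H5Quiet {
  H5Quiet() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }
};
static H5Quiet quiet_init;

void write_string_attr(hid_t obj, const char *name, const std::string &value) {
  hid_t space = H5Screate(H5S_SCALAR);
  hid_t type = H5Tcopy(H5T_C_S1);
  H5Tset_size(type, value.size() + 1);
  H5Tset_strpad(type, H5T_STR_NULLTERM);
  hid_t attr = H5Acreate2(obj, name, type, space, H5P_DEFAULT, H5P_DEFAULT);
  if (attr < 0) stop("HDF5: cannot create attribute '%s'", name);
  H5Awrite(attr, type, value.c_str());
  H5Aclose(attr); H5Tclose(type); H5Sclose(space);
}

std::string read_string_attr(hid_t obj, const char *name) {
  hid_t attr = H5Aopen(obj, name, H5P_DEFAULT);
  if (attr < 0) stop("format error: missing attribute '%s'", name);
  hid_t type = H5Aget_type(attr);
  std::string out;
  if (H5Tis_variable_str(type) > 0) {
    char *buf = NULL;
    hid_t mtype = H5Tcopy(H5T_C_S1);
    H5Tset_size(mtype, H5T_VARIABLE);
    H5Aread(attr, mtype, &buf);
    if (buf) { out = buf; free(buf); }
    H5Tclose(mtype);
  } else {
    size_t sz = H5Tget_size(type);
    std::vector<char> buf(sz + 1, '\0');
    hid_t mtype = H5Tcopy(H5T_C_S1);
    H5Tset_size(mtype, sz + 1);
    H5Tset_strpad(mtype, H5T_STR_NULLTERM);
    H5Aread(attr, mtype, buf.data());
    out = buf.data();
    H5Tclose(mtype);
  }
  H5Tclose(type); H5Aclose(attr);
  return out;
}

herr_t collect_attr_names(hid_t, const char *name, const H5A_info_t *,
                          void *op_data) {
  static_cast<std::vector<std::string> *>(op_data)->push_back(name);
  return 0;
}

} // namespace

// [[Rcpp::export]]
void cpp_h5_write_cube(std::string path, NumericVector wavenumbers,
                       NumericVector data_c, IntegerVector dims,
                       double pixel_size, std::string modality,
                       CharacterVector prov) {
  hid_t file = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (file < 0) stop("I/O error: cannot create HDF5 file '%s'", path.c_str());

  // root attributes
  {
    hid_t space = H5Screate(H5S_SCALAR);
    hid_t attr = H5Acreate2(file, "format_version", H5T_NATIVE_INT, space,
                            H5P_DEFAULT, H5P_DEFAULT);
    int ver = 1;
    H5Awrite(attr, H5T_NATIVE_INT, &ver);
    H5Aclose(attr);
    attr = H5Acreate2(file, "pixel_size_um", H5T_NATIVE_DOUBLE, space,
                      H5P_DEFAULT, H5P_DEFAULT);
    H5Awrite(attr, H5T_NATIVE_DOUBLE, &pixel_size);
    H5Aclose(attr); H5Sclose(space);
    write_string_attr(file, "modality", modality);
  }

  // wavenumbers
  {
    hsize_t n = (hsize_t)wavenumbers.size();
    hid_t space = H5Screate_simple(1, &n, NULL);
    hid_t dset = H5Dcreate2(file, "/wavenumbers_cm1", H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             REAL(wavenumbers));
    H5Dclose(dset); H5Sclose(space);
  }

  // absorbance (C order: rows, cols, n_wn with n_wn fastest)
  {
    hsize_t d[3] = {(hsize_t)dims[0], (hsize_t)dims[1], (hsize_t)dims[2]};
    hid_t space = H5Screate_simple(3, d, NULL);
    hid_t dset = H5Dcreate2(file, "/absorbance", H5T_NATIVE_DOUBLE, space,
                            H5P_DEFAULT, H5P_DEFAULT, H5P_DEFAULT);
    H5Dwrite(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
             REAL(data_c));
    H5Dclose(dset); H5Sclose(space);
  }

  // provenance group with one string attribute per entry (names keep order)
  {
    hid_t grp = H5Gcreate2(file, "/provenance", H5P_DEFAULT, H5P_DEFAULT,
                           H5P_DEFAULT);
    for (int i = 0; i < prov.size(); ++i) {
      char name[32];
      snprintf(name, sizeof(name), "entry_%06d", i);
      write_string_attr(grp, name, as<std::string>(prov[i]));
    }
    H5Gclose(grp);
  }

  H5Fclose(file);
}

// [[Rcpp::export]]
List cpp_h5_read_cube(std::string path) {
  hid_t file = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (file < 0) stop("I/O error: cannot open HDF5 file '%s'", path.c_str());

  if (H5Aexists(file, "format_version") <= 0) {
    H5Fclose(file);
    stop("format error: missing attribute 'format_version'");
  }
  if (H5Aexists(file, "pixel_size_um") <= 0) {
    H5Fclose(file);
    stop("format error: missing attribute 'pixel_size_um'");
  }
  if (H5Aexists(file, "modality") <= 0) {
    H5Fclose(file);
    stop("format error: missing attribute 'modality'");
  }

  int version = 0;
  double pixel_size = 0;
  {
    hid_t attr = H5Aopen(file, "format_version", H5P_DEFAULT);
    H5Aread(attr, H5T_NATIVE_INT, &version);
    H5Aclose(attr);
    attr = H5Aopen(file, "pixel_size_um", H5P_DEFAULT);
    H5Aread(attr, H5T_NATIVE_DOUBLE, &pixel_size);
    H5Aclose(attr);
  }
  std::string modality = read_string_attr(file, "modality");

  if (H5Lexists(file, "/wavenumbers_cm1", H5P_DEFAULT) <= 0) {
    H5Fclose(file);
    stop("format error: missing dataset '/wavenumbers_cm1'");
  }
  if (H5Lexists(file, "/absorbance", H5P_DEFAULT) <= 0) {
    H5Fclose(file);
    stop("format error: missing dataset '/absorbance'");
  }

  NumericVector wn;
  {
    hid_t dset = H5Dopen2(file, "/wavenumbers_cm1", H5P_DEFAULT);
    hid_t space = H5Dget_space(dset);
    hsize_t n;
    H5Sget_simple_extent_dims(space, &n, NULL);
    wn = NumericVector((R_xlen_t)n);
    H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(wn));
    H5Sclose(space); H5Dclose(dset);
  }

  NumericVector data;
  IntegerVector dims(3);
  {
    hid_t dset = H5Dopen2(file, "/absorbance", H5P_DEFAULT);
    hid_t space = H5Dget_space(dset);
    int rank = H5Sget_simple_extent_ndims(space);
    if (rank != 3) {
      H5Sclose(space); H5Dclose(dset); H5Fclose(file);
      stop("format error: '/absorbance' must be 3-D (rows x cols x n_wn)");
    }
    hsize_t d[3];
    H5Sget_simple_extent_dims(space, d, NULL);
    dims[0] = (int)d[0]; dims[1] = (int)d[1]; dims[2] = (int)d[2];
    data = NumericVector((R_xlen_t)(d[0] * d[1] * d[2]));
    H5Dread(dset, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT, REAL(data));
    H5Sclose(space); H5Dclose(dset);
  }

  CharacterVector prov;
  if (H5Lexists(file, "/provenance", H5P_DEFAULT) > 0) {
    hid_t grp = H5Gopen2(file, "/provenance", H5P_DEFAULT);
    std::vector<std::string> names;
    hsize_t idx = 0;
    H5Aiterate2(grp, H5_INDEX_NAME, H5_ITER_INC, &idx, collect_attr_names,
                &names);
    std::sort(names.begin(), names.end());
    prov = CharacterVector(names.size());
    for (size_t i = 0; i < names.size(); ++i)
      prov[i] = read_string_attr(grp, names[i].c_str());
    H5Gclose(grp);
  }

  H5Fclose(file);
  return List::create(_["format_version"] = version,
                      _["pixel_size_um"] = pixel_size,
                      _["modality"] = modality,
                      _["wavenumbers"] = wn,
                      _["data_c"] = data,
                      _["dims"] = dims,
                      _["provenance"] = prov);
}
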