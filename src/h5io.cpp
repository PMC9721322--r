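// Minimal HDF5 reader/writer for frame stacks, masks and attributes.
//
// Buffers cross the R/C++ boundary in the file's C (row-major) element
// order; the R wrappers permute arrays so that dataset shapes on disk follow
// the (T, H, W) / (T, cell, H, W) convention of facility files and round-trip
// with h5py.

#include <Rcpp.h>
#include <hdf5.h>

#include <string>
#include <vector>

using namespace Rcpp;

namespace {

struct Hid {
  hid_t id;
  herr_t (*closer)(hid_t);
  Hid(hid_t i, herr_t (*c)(hid_t)) : id(i), closer(c) {}
  ~Hid() {
    if (id >= 0 && closer) closer(id);
  }
  operator hid_t() const { return id; }
};

void quiet_errors() { H5Eset_auto2(H5E_DEFAULT, NULL, NULL); }

hid_t open_file(const std::string& path, bool rdwr) {
  quiet_errors();
  hid_t f = H5Fopen(path.c_str(), rdwr ? H5F_ACC_RDWR : H5F_ACC_RDONLY,
                    H5P_DEFAULT);
  if (f < 0) stop("cannot open HDF5 file '%s'", path.c_str());
  return f;
}

}  // namespace

// [[Rcpp::export]]
void cpp_h5_create(std::string path) {
  quiet_errors();
  hid_t f = H5Fcreate(path.c_str(), H5F_ACC_TRUNC, H5P_DEFAULT, H5P_DEFAULT);
  if (f < 0) stop("cannot create HDF5 file '%s'", path.c_str());
  H5Fclose(f);
}

// [[Rcpp::export]]
bool cpp_h5_exists(std::string path, std::string name) {
  quiet_errors();
  hid_t f = H5Fopen(path.c_str(), H5F_ACC_RDONLY, H5P_DEFAULT);
  if (f < 0) return false;
  Hid fh(f, H5Fclose);
  // check every component of the path
  std::string part;
  for (size_t i = 0; i < name.size(); ++i) {
    if (name[i] == '/') {
      if (!part.empty() &&
          H5Lexists(fh, part.c_str(), H5P_DEFAULT) <= 0)
        return false;
    }
    part += name[i];
  }
  return H5Lexists(fh, part.c_str(), H5P_DEFAULT) > 0;
}

// data arrives in the file's C element order; dims are the file dims
// [[Rcpp::export]]
void cpp_h5_write(std::string path, std::string dataset, SEXP data,
                  IntegerVector dims, std::string dtype) {
  quiet_errors();
  Hid f(open_file(path, true), H5Fclose);

  int rank = dims.size();
  std::vector<hsize_t> hd(rank);
  R_xlen_t n = 1;
  for (int i = 0; i < rank; ++i) {
    hd[i] = static_cast<hsize_t>(dims[i]);
    n *= dims[i];
  }

  if (H5Lexists(f, dataset.c_str(), H5P_DEFAULT) > 0)
    H5Ldelete(f, dataset.c_str(), H5P_DEFAULT);

  Hid space(H5Screate_simple(rank, hd.data(), NULL), H5Sclose);
  Hid lcpl(H5Pcreate(H5P_LINK_CREATE), H5Pclose);
  H5Pset_create_intermediate_group(lcpl, 1);

  hid_t ftype = (dtype == "uint8") ? H5T_STD_U8LE : H5T_IEEE_F64LE;
  Hid ds(H5Dcreate2(f, dataset.c_str(), ftype, space, lcpl, H5P_DEFAULT,
                    H5P_DEFAULT),
         H5Dclose);
  if (ds < 0) stop("cannot create dataset '%s'", dataset.c_str());

  herr_t st;
  if (dtype == "uint8") {
    IntegerVector iv(data);
    if (iv.size() != n) stop("data length does not match dims");
    std::vector<unsigned char> buf(n);
    for (R_xlen_t i = 0; i < n; ++i) {
      int v = iv[i];
      buf[i] = static_cast<unsigned char>(v < 0 ? 0 : (v > 255 ? 255 : v));
    }
    st = H5Dwrite(ds, H5T_NATIVE_UCHAR, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                  buf.data());
  } else {
    NumericVector nv(data);
    if (nv.size() != n) stop("data length does not match dims");
    st = H5Dwrite(ds, H5T_NATIVE_DOUBLE, H5S_ALL, H5S_ALL, H5P_DEFAULT,
                  REAL(nv));
  }
  if (st < 0) stop("write to dataset '%s' failed", dataset.c_str());
}

// [[Rcpp::export]]
List cpp_h5_dims(std::string path, std::string dataset) {
  quiet_errors();
  Hid f(open_file(path, false), H5Fclose);
  if (H5Lexists(f, dataset.c_str(), H5P_DEFAULT) <= 0)
    stop("dataset '%s' not found in '%s'", dataset.c_str(), path.c_str());
  Hid ds(H5Dopen2(f, dataset.c_str(), H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("cannot open dataset '%s'", dataset.c_str());
  Hid sp(H5Dget_space(ds), H5Sclose);
  int rank = H5Sget_simple_extent_ndims(sp);
  std::vector<hsize_t> hd(rank);
  H5Sget_simple_extent_dims(sp, hd.data(), NULL);
  IntegerVector dims(rank);
  for (int i = 0; i < rank; ++i) dims[i] = static_cast<int>(hd[i]);
  return List::create(_["dims"] = dims);
}

// read full dataset, or one index of one axis (0-based, C order)
// [[Rcpp::export]]
List cpp_h5_read(std::string path, std::string dataset, int sel_axis,
                 int sel_index) {
  quiet_errors();
  Hid f(open_file(path, false), H5Fclose);
  if (H5Lexists(f, dataset.c_str(), H5P_DEFAULT) <= 0)
    stop("dataset '%s' not found in '%s'", dataset.c_str(), path.c_str());
  Hid ds(H5Dopen2(f, dataset.c_str(), H5P_DEFAULT), H5Dclose);
  if (ds < 0) stop("cannot open dataset '%s'", dataset.c_str());
  Hid fspace(H5Dget_space(ds), H5Sclose);
  int rank = H5Sget_simple_extent_ndims(fspace);
  std::vector<hsize_t> hd(rank);
  H5Sget_simple_extent_dims(fspace, hd.data(), NULL);

  std::vector<hsize_t> start(rank, 0), count(hd);
  if (sel_axis >= 0) {
    if (sel_axis >= rank) stop("selection axis exceeds dataset rank");
    if (sel_index < 0 || sel_index >= static_cast<int>(hd[sel_axis]))
      stop("selection index out of range for axis %d (size %d)", sel_axis,
           static_cast<int>(hd[sel_axis]));
    start[sel_axis] = sel_index;
    count[sel_axis] = 1;
    H5Sselect_hyperslab(fspace, H5S_SELECT_SET, start.data(), NULL,
                        count.data(), NULL);
  }
  R_xlen_t n = 1;
  IntegerVector out_dims(rank);
  for (int i = 0; i < rank; ++i) {
    out_dims[i] = static_cast<int>(count[i]);
    n *= count[i];
  }
  Hid mspace(H5Screate_simple(rank, count.data(), NULL), H5Sclose);
  NumericVector buf(n);
  herr_t st = H5Dread(ds, H5T_NATIVE_DOUBLE, mspace, fspace, H5P_DEFAULT,
                      REAL(buf));
  if (st < 0) stop("read from dataset '%s' failed", dataset.c_str());
  return List::create(_["data"] = buf, _["dims"] = out_dims);
}

// [[Rcpp::export]]
void cpp_h5_write_attr(std::string path, std::string object, std::string name,
                       SEXP value) {
  quiet_errors();
  Hid f(open_file(path, true), H5Fclose);
  Hid obj(H5Oopen(f, object.c_str(), H5P_DEFAULT), H5Oclose);
  if (obj < 0) stop("object '%s' not found", object.c_str());
  if (H5Aexists(obj, name.c_str()) > 0) H5Adelete(obj, name.c_str());

  if (TYPEOF(value) == STRSXP) {
    std::string s = as<std::string>(value);
    Hid type(H5Tcopy(H5T_C_S1), H5Tclose);
    H5Tset_size(type, s.size() > 0 ? s.size() : 1);
    H5Tset_strpad(type, H5T_STR_NULLPAD);
    Hid sp(H5Screate(H5S_SCALAR), H5Sclose);
    Hid a(H5Acreate2(obj, name.c_str(), type, sp, H5P_DEFAULT, H5P_DEFAULT),
          H5Aclose);
    H5Awrite(a, type, s.c_str());
  } else {
    NumericVector v(value);
    hsize_t n = v.size();
    Hid sp(n == 1 ? H5Screate(H5S_SCALAR) : H5Screate_simple(1, &n, NULL),
           H5Sclose);
    Hid a(H5Acreate2(obj, name.c_str(), H5T_IEEE_F64LE, sp, H5P_DEFAULT,
                     H5P_DEFAULT),
          H5Aclose);
    H5Awrite(a, H5T_NATIVE_DOUBLE, REAL(v));
  }
}

// [[Rcpp::export]]
SEXP cpp_h5_read_attr(std::string path, std::string object, std::string name) {
  quiet_errors();
  Hid f(open_file(path, false), H5Fclose);
  Hid obj(H5Oopen(f, object.c_str(), H5P_DEFAULT), H5Oclose);
  if (obj < 0) stop("object '%s' not found", object.c_str());
  if (H5Aexists(obj, name.c_str()) <= 0)
    stop("attribute '%s' not found on '%s'", name.c_str(), object.c_str());
  Hid a(H5Aopen(obj, name.c_str(), H5P_DEFAULT), H5Aclose);
  Hid type(H5Aget_type(a), H5Tclose);
  H5T_class_t cls = H5Tget_class(type);
  if (cls == H5T_STRING) {
    size_t sz = H5Tget_size(type);
    if (H5Tis_variable_str(type) > 0) {
      char* p = NULL;
      Hid mt(H5Tcopy(H5T_C_S1), H5Tclose);
      H5Tset_size(mt, H5T_VARIABLE);
      H5Aread(a, mt, &p);
      std::string s(p ? p : "");
      if (p) H5free_memory(p);
      return wrap(s);
    }
    std::vector<char> buf(sz + 2, '\0');
    Hid mt(H5Tcopy(H5T_C_S1), H5Tclose);
    H5Tset_size(mt, sz + 1);  // room for the terminator the conversion adds
    H5Aread(a, mt, buf.data());
    return wrap(std::string(buf.data(), strnlen(buf.data(), sz + 1)));
  }
  Hid sp(H5Aget_space(a), H5Sclose);
  hssize_t n = H5Sget_simple_extent_npoints(sp);
  NumericVector out(n);
  H5Aread(a, H5T_NATIVE_DOUBLE, REAL(out));
  return out;
}

// names of links inside a group
// [[Rcpp::export]]
CharacterVector cpp_h5_ls(std::string path, std::string group) {
  quiet_errors();
  Hid f(open_file(path, false), H5Fclose);
  Hid g(H5Gopen2(f, group.c_str(), H5P_DEFAULT), H5Gclose);
  if (g < 0) stop("group '%s' not found", group.c_str());
  H5G_info_t info;
  H5Gget_info(g, &info);
  CharacterVector out(info.nlinks);
  for (hsize_t i = 0; i < info.nlinks; ++i) {
    ssize_t len = H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_NATIVE, i,
                                     NULL, 0, H5P_DEFAULT);
    std::vector<char> buf(len + 1, '\0');
    H5Lget_name_by_idx(g, ".", H5_INDEX_NAME, H5_ITER_NATIVE, i, buf.data(),
                       len + 1, H5P_DEFAULT);
    out[i] = std::string(buf.data());
  }
  return out;
}
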