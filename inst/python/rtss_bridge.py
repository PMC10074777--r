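"""Bridge between DICOM RT Structure Sets and the json-contours dialect.

Usage:
    python rtss_bridge.py to-json   <rtss.dcm>  <out.json>
    python rtss_bridge.py from-json <in.json>   <rtss.dcm>

Coordinates pass through unchanged (DICOM patient coordinates, mm).
"""

import hashlib
import json
import sys

import pydicom
from pydicom.dataset import Dataset, FileDataset, FileMetaDataset
from pydicom.uid import ExplicitVRLittleEndian

RTSS_SOP_CLASS = "1.2.840.10008.5.1.4.1.1.481.3"


def deterministic_uid(seed: str) -> str:
    # Content-derived UID so identical inputs serialize identically.
    return "2.25." + str(int(hashlib.md5(seed.encode()).hexdigest(), 16) % 10**30)


def to_json(rtss_path: str, json_path: str) -> None:
    ds = pydicom.dcmread(rtss_path)
    names = {}
    frame = ""
    for roi in getattr(ds, "StructureSetROISequence", []):
        names[int(roi.ROINumber)] = str(roi.ROIName)
        frame = str(getattr(roi, "ReferencedFrameOfReferenceUID", frame))
    structures = []
    for rc in getattr(ds, "ROIContourSequence", []):
        num = int(rc.ReferencedROINumber)
        contours = []
        for c in getattr(rc, "ContourSequence", []):
            data = [float(v) for v in c.ContourData]
            pts = [data[i : i + 3] for i in range(0, len(data), 3)]
            contours.append(pts)
        structures.append({"name": names.get(num, f"ROI_{num}"), "contours": contours})
    doc = {
        "format": "json-contours",
        "version": "1.0",
        "patient_id": str(getattr(ds, "PatientID", "")),
        "frame_of_reference": frame,
        "structures": structures,
    }
    with open(json_path, "w") as fh:
        json.dump(doc, fh)


def from_json(json_path: str, rtss_path: str) -> None:
    with open(json_path) as fh:
        doc = json.load(fh)
    if doc.get("format") != "json-contours":
        raise ValueError("input is not a json-contours document")

    content_key = json.dumps(doc, sort_keys=True)
    meta = FileMetaDataset()
    meta.MediaStorageSOPClassUID = RTSS_SOP_CLASS
    meta.MediaStorageSOPInstanceUID = deterministic_uid("sop:" + content_key)
    meta.TransferSyntaxUID = ExplicitVRLittleEndian

    ds = FileDataset(rtss_path, {}, file_meta=meta, preamble=b"\0" * 128)
    ds.SOPClassUID = RTSS_SOP_CLASS
    ds.SOPInstanceUID = meta.MediaStorageSOPInstanceUID
    ds.Modality = "RTSTRUCT"
    ds.PatientID = doc.get("patient_id", "")
    ds.PatientName = doc.get("patient_id", "")
    ds.StructureSetLabel = "lesionwise"
    frame = doc.get("frame_of_reference") or deterministic_uid("for:" + content_key)

    ds.StructureSetROISequence = []
    ds.ROIContourSequence = []
    for num, s in enumerate(doc.get("structures", []), start=1):
        roi = Dataset()
        roi.ROINumber = num
        roi.ROIName = s["name"]
        roi.ReferencedFrameOfReferenceUID = frame
        roi.ROIGenerationAlgorithm = ""
        ds.StructureSetROISequence.append(roi)

        rc = Dataset()
        rc.ReferencedROINumber = num
        rc.ContourSequence = []
        for pts in s.get("contours", []):
            c = Dataset()
            c.ContourGeometricType = "CLOSED_PLANAR"
            c.NumberOfContourPoints = len(pts)
            c.ContourData = [f"{v:.6f}" for p in pts for v in p]
            rc.ContourSequence.append(c)
        ds.ROIContourSequence.append(rc)

    ds.save_as(rtss_path, enforce_file_format=True)


def main(argv) -> int:
    if len(argv) != 4 or argv[1] not in {"to-json", "from-json"}:
        sys.stderr.write(__doc__)
        return 2
    if argv[1] == "to-json":
        to_json(argv[2], argv[3])
    else:
        from_json(argv[2], argv[3])
    return 0


if __name__ == "__main__":
    sys.exit(main(sys.argv))
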