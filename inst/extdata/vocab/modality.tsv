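# vocabulary: MODALITY
# dicom_tag: (0008,0060)
# edition: DICOM PS3.3 C.7.3.1.1.1 Modality defined terms, pinned edition with 54 terms
code_value	meaning
AU	Audio
BDUS	Bone Densitometry (ultrasound)
BI	Biomagnetic imaging
BMD	Bone Densitometry (X-Ray)
CR	Computed Radiography
CT	Computed Tomography
DG	Diaphanography
DX	Digital Radiography
ECG	Electrocardiography
EPS	Cardiac Electrophysiology
ES	Endoscopy
GM	General Microscopy
HD	Hemodynamic Waveform
IO	Intra-Oral Radiography
IOL	Intraocular Lens Data
IVOCT	Intravascular Optical Coherence Tomography
IVUS	Intravascular Ultrasound
KER	Keratometry
KO	Key Object Selection
LEN	Lensometry
LS	Laser surface scan
MG	Mammography
MR	Magnetic Resonance
NM	Nuclear Medicine
OAM	Ophthalmic Axial Measurements
OCT	Optical Coherence Tomography (non-Ophthalmic)
OP	Ophthalmic Photography
OPM	Ophthalmic Mapping
OPT	Ophthalmic Tomography
OPV	Ophthalmic Visual Field
OSS	Optical Surface Scan
OT	Other
PR	Presentation State
PT	Positron emission tomography (PET)
PX	Panoramic X-Ray
REG	Registration
RESP	Respiratory Waveform
RF	Radio Fluoroscopy
RG	Radiographic imaging (conventional film/screen)
RTDOSE	Radiotherapy Dose
RTIMAGE	Radiotherapy Image
RTPLAN	Radiotherapy Plan
RTRECORD	RT Treatment Record
RTSTRUCT	Radiotherapy Structure Set
SEG	Segmentation
SM	Slide Microscopy
SR	SR Document
SRF	Subjective Refraction
STAIN	Automated Slide Stainer
TG	Thermography
US	Ultrasound
VA	Visual Acuity
XA	X-Ray Angiography
XC	External-camera Photography
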