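term	semantic_type
fistula	Anatomical Abnormality
stenosis	Anatomical Abnormality
hernia	Acquired Abnormality
aneurysm	Acquired Abnormality
l transposition	Congenital Abnormality
spina bifida	Congenital Abnormality
atrial septal defect	Congenital Abnormality
breast	Body Part Organ or Organ Component
left breast	Body Part Organ or Organ Component
arteries	Body Part Organ or Organ Component
symphysis	Body Part Organ or Organ Component
liver	Body Part Organ or Organ Component
skull	Body Part Organ or Organ Component
pleural fluid	Body Substance
cerebrospinal fluid	Body Substance
skeletal system	Body System
nervous system	Body System
soft tissue	Tissue
adipose tissue	Tissue
red blood cells	Cell
macrophages	Cell
brca1 gene	Gene or Genome
tp53 gene	Gene or Genome
estrogen receptor	Receptor
her2 receptor	Receptor
birads category	Classification
lung rads score	Classification
outcome	Functional Concept
differential	Functional Concept
right	Spatial Concept
midline	Spatial Concept
bilateral	Spatial Concept
t9	Body Location or Region
abdomen	Body Location or Region
left upper quadrant	Body Location or Region
joint space	Body Space or Junction
pleural cavity	Body Space or Junction
ivu films	Diagnostic Procedure
ct scan	Diagnostic Procedure
ultrasound	Diagnostic Procedure
mri	Diagnostic Procedure
mastectomy	Therapeutic or Preventive Procedure
drainage	Therapeutic or Preventive Procedure
radiotherapy	Therapeutic or Preventive Procedure
biopsy	Laboratory Procedure
blood culture	Laboratory Procedure
follow up	Health Care Activity
clinical review	Health Care Activity
clinical trial	Research Activity
case study	Research Activity
screening	Activity
monitoring	Activity
cardiac pacemaker	Medical Device
stent	Medical Device
catheter	Medical Device
prosthesis	Manufactured Object
surgical clip	Manufactured Object
foci	Finding
separated pubic bones	Finding
mass lesion	Finding
radiotracer uptake	Finding
pain	Sign or Symptom
breast pain	Sign or Symptom
erythema	Sign or Symptom
tenderness	Sign or Symptom
headache	Sign or Symptom
fracture	Injury or Poisoning
contusion	Injury or Poisoning
elevated esr	Laboratory or Test Result
positive culture	Laboratory or Test Result
calcification	Phenomenon or Process
enhancement	Phenomenon or Process
breast cancer	Disease or Syndrome
pneumonia	Disease or Syndrome
fibroadenoma	Neoplastic Process
lymphoma	Neoplastic Process
haemangiomas	Neoplastic Process
benign vascular tumors	Neoplastic Process
anxiety disorder	Mental or Behavioral Dysfunction
dementia	Mental or Behavioral Dysfunction
dysplasia	Cell or Molecular Dysfunction
metaplasia	Cell or Molecular Dysfunction
thrombosis	Pathologic Function
vessel thrombosis	Pathologic Function
effusion	Pathologic Function
complications	Pathologic Function
phagocytosis	Cell Function
apoptosis	Cell Function
perfusion	Organ or Tissue Function
peristalsis	Organ or Tissue Function
respiration	Organism Function
metabolism	Organism Function
uptake	Physiologic Function
circulation	Physiologic Function
benign	Qualitative Concept
severe	Qualitative Concept
multiple	Quantitative Concept
two	Quantitative Concept
chronic	Temporal Concept
acute	Temporal Concept
previous history	Temporal Concept
contrast agent	Pharmacologic Substance
gadolinium	Pharmacologic Substance
fluid	Substance
gas	Substance
haemoglobin	Biologically Active Substance
bilirubin	Biologically Active Substance
bone cement	Biomedical or Dental Material
dental amalgam	Biomedical or Dental Material
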