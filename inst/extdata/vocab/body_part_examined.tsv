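# vocabulary: BODY_PART
# dicom_tag: (0018,0015)
# edition: DICOM PS3.16 Annex L Body Part Examined defined terms, pinned edition with 116 terms
code_value	meaning
ABDOMEN	Abdomen
ABDOMENPELVIS	Abdomen and Pelvis
ADRENAL	Adrenal gland
ANKLE	Ankle joint
AORTA	Aorta
AXILLA	Axilla
BACK	Back
BLADDER	Bladder
BRAIN	Brain
BREAST	Breast
BRONCHUS	Bronchus
BUTTOCK	Buttock
CALCANEUS	Calcaneus
CALF	Calf of leg
CAROTID	Carotid artery
CEREBELLUM	Cerebellum
CERVIX	Cervix
CHEEK	Cheek
CHEST	Chest
CHESTABDOMEN	Chest and Abdomen
CHESTABDPELVIS	Chest, Abdomen and Pelvis
CIRCLEOFWILLIS	Circle of Willis
CLAVICLE	Clavicle
COCCYX	Coccyx
COLON	Colon
CORNEA	Cornea
CORONARYARTERY	Coronary artery
CSPINE	Cervical spine
CTSPINE	Cervico-thoracic spine
DUODENUM	Duodenum
EAR	Ear
ELBOW	Elbow joint
ESOPHAGUS	Esophagus
EXTREMITY	Extremity
EYE	Eye
EYELID	Eyelid
FACE	Face
FEMUR	Femur
FINGER	Finger
FOOT	Foot
FOREARM	Forearm
GALLBLADDER	Gallbladder
HAND	Hand
HEAD	Head
HEADNECK	Head and Neck
HEART	Heart
HIP	Hip joint
HUMERUS	Humerus
IAC	Internal auditory canal
ILEUM	Ileum
ILIUM	Ilium
JAW	Jaw region
JEJUNUM	Jejunum
KIDNEY	Kidney
KNEE	Knee
LARYNX	Larynx
LEG	Leg
LIVER	Liver
LSPINE	Lumbar spine
LSSPINE	Lumbo-sacral spine
LUNG	Lung
MANDIBLE	Mandible
MAXILLA	Maxilla
MEDIASTINUM	Mediastinum
MOUTH	Mouth
NECK	Neck
NECKCHEST	Neck and Chest
NECKCHESTABDOMEN	Neck, Chest and Abdomen
NECKCHESTABDPELV	Neck, Chest, Abdomen and Pelvis
NOSE	Nose
ORBIT	Orbital region
OVARY	Ovary
PANCREAS	Pancreas
PAROTID	Parotid gland
PATELLA	Patella
PELVIS	Pelvis
PENIS	Penis
PHARYNX	Pharynx
PROSTATE	Prostate
RADIUS	Radius
RADIUSULNA	Radius and ulna
RECTUM	Rectum
RIB	Rib
SCALP	Scalp
SCAPULA	Scapula
SCLERA	Sclera
SCROTUM	Scrotum
SHOULDER	Shoulder
SKULL	Skull
SPINE	Spine
SPLEEN	Spleen
SSPINE	Sacral spine
STERNUM	Sternum
STOMACH	Stomach
SUBMANDIBULAR	Submandibular gland
TESTIS	Testis
THIGH	Thigh
THUMB	Thumb
THYMUS	Thymus
THYROID	Thyroid
TIBIA	Tibia
TIBIAFIBULA	Tibia and fibula
TLSPINE	Thoraco-lumbar spine
TMJ	Temporomandibular joint
TOE	Toe
TONGUE	Tongue
TRACHEA	Trachea
TSPINE	Thoracic spine
ULNA	Ulna
URETER	Ureter
URETHRA	Urethra
UTERUS	Uterus
VAGINA	Vagina
VULVA	Vulva
WRIST	Wrist joint
ZYGOMA	Zygoma
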