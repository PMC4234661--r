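id,name,density_kg_m3,speed_m_s,atten_db_cm_mhz
0,"Air @ 25C, 60% Rel. Hum",1.2,347,0.012
1,"Int. Air @ 30C, 90% RH",1.15,351,0.012
12,"Brain (Grey Matter)",1045,1562,0.625
28,"Blood Vessel",1102,1584,0.2
32,"Brain (White Matter)",1041,1562,1.05
72,"Cornea",1051,1588,0.5
80,"Cerebrospinal fluid",1007,1528,0.5
84,"Bone (Cortical)",1908,2740,20
92,"Bone (Marrow)",1029,1560,5
96,"Eye (Sclera)",1032,1560,0.5
104,"Lung",722,1125,0.5
112,"Cartilage",1100,1729,0.5
116,"Eye (Lens)",1076,1656,2.0
124,"Dura",1174,1563,0.5
136,"Fat",911,1450,0.65
144,"Esophagus",1040,1562,0.5
152,"Gland",1050,1570,0.5
156,"Tongue",1090,1562,0.5
168,"Lymph",1035,1570,0.5
172,"Teeth",2063,4695,20
180,"Muscle",1090,1579,3.3
184,"Spinal cord",1075,1562,0.5
192,"Nerve",1075,1562,1.55
196,"Eye (Vitreous Humor)",1009,1528,0.1
204,"Skin",1100,1729,0.8
208,"Mucosa",1102,1570,0.5
216,"Trachea",1080,1729,0.5
220,"Tendon/Ligament",1142,1729,4.7
255,"Soft tissue",1000,1540,0.5
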