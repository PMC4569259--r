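case_id,sex,age,location,histology,who_grade
1,F,22,right temporal lobe,astrocytoma,II
2,M,46,left temporal lobe,astrocytoma,II
3,F,31,right frontal lobe,astrocytoma,II
4,M,23,left thalamus,astrocytoma,II
5,M,55,left temporal lobe,astrocytoma,II
6,F,22,left parietal lobe,astrocytoma,II
7,M,35,left frontal lobe,astrocytoma,II
8,F,36,left temporal lobe,astrocytoma,II
9,M,55,right frontal lobe,astrocytoma,II
10,M,33,right frontal lobe,astrocytoma,II
11,M,59,left insular lobe,astrocytoma,II
12,M,10,right frontal lobe,astrocytoma,II
13,M,56,right frontal-temporal lobe,astrocytoma,II
14,M,61,right frontal-temporal lobe,astrocytoma,II
15,F,40,bilateral frontal-parietal-occipital lobe,astrocytoma,II
16,F,36,left frontal-temporal lobe,astrocytoma,II
17,M,13,right basal ganglia,astrocytoma,II
18,M,19,left frontal lobe/left basal ganglia and septum pellucidum,astrocytoma,II
19,M,14,right frontal lobe,mixed glioma/neuronal tumor,II
20,M,50,left frontal lobe,oligodendro-astrocytoma,II
21,M,32,left frontal lobe,oligodendro-astrocytoma,II
22,M,42,right frontal lobe,oligodendro-astrocytoma,II
23,F,38,right frontal lobe,oligodendro-astrocytoma,II
24,M,35,right frontal lobe,oligodendro-astrocytoma,II
25,M,38,left parietal-occipital lobe,oligodendro-astrocytoma,II
26,M,27,left temporal lobe,oligodendro-astrocytoma,II
27,F,46,right frontal-temporal lobe,oligodendro-astrocytoma,II
28,M,41,left temporal-parietal lobe,oligodendro-astrocytoma,II
29,M,65,left temporal lobe,oligodendro-astrocytoma,II
30,M,34,left temporal lobe,oligodendro-astrocytoma,II
31,M,41,bilateral frontal-parietal lobe,oligodendro-astrocytoma,II
32,F,48,left parietal lobe,oligodendroglioma,II
33,M,44,right frontal lobe,oligodendroglioma,II
34,M,43,left frontal lobe,oligodendroglioma,II
35,M,40,right frontal-parietal lobe,oligodendroglioma,II
36,M,56,right frontal lobe,oligodendroglioma,II
37,F,45,right frontal-insular lobe,anaplastic oligodendro-astrocytoma,III
38,F,58,left frontal-insular lobe,anaplastic oligodendro-astrocytoma,III
39,F,24,right parietal lobe/corpus callosum,anaplastic oligodendro-astrocytoma,III
40,M,40,right frontal-insular lobe,anaplastic oligodendro-astrocytoma,III
41,F,29,right frontal lobe,anaplastic oligodendro-astrocytoma,III
42,M,58,left insular lobe,anaplastic oligodendro-astrocytoma,III
43,F,23,corpus callosum and bilateral frontal-parietal lobe,anaplastic oligodendro-astrocytoma,III
44,F,55,right thalamus,anaplastic oligodendro-astrocytoma,III
45,F,40,left frontal lobe,anaplastic oligodendro-astrocytoma,III
46,M,63,bilateral frontal lobe and corpus callosum,anaplastic oligodendro-astrocytoma,III
47,M,54,left temporal lobe,astrocytoma,III
48,F,53,right frontal lobe and bilateral temporal lobe,astrocytoma,III
49,M,44,right parietal lobe,astrocytoma,III
50,F,42,right temporal lobe,astrocytoma,III
51,F,54,left temporal lobe,astrocytoma,III
52,M,33,right temporal lobe,astrocytoma,III
53,F,52,left thalamus,astrocytoma,III
54,M,34,the third ventricle,glioblastoma,III
55,F,68,right frontal-insular lobe,glioblastoma,IV
56,M,63,left frontal lobe,glioblastoma,IV
57,M,64,left parietal-occipital lobe,glioblastoma,IV
58,F,44,right parietal-occipital lobe,glioblastoma,IV
59,M,40,left temporal lobe,glioblastoma,IV
60,M,48,left frontal-temporal-insular lobe,glioblastoma,IV
61,F,48,right parietal lobe,glioblastoma,IV
62,F,57,left temporal lobe,glioblastoma,IV
63,M,73,left frontal lobe,glioblastoma,IV
64,F,62,left parietal lobe,glioblastoma,IV
65,M,53,left frontal lobe,glioblastoma,IV
66,M,64,right temporal-parietal lobe,glioblastoma,IV
67,M,64,left parietal-occipital lobe,glioblastoma,IV
68,M,49,left parietal lobe/corpus callosum,glioblastoma,IV
69,M,52,bilateral frontal lobe and the knee of corpus callosum,glioblastoma,IV
70,F,45,right frontal lobe,glioblastoma,IV
71,M,60,right parietal-occipital lobe,glioblastoma,IV
72,F,57,left temporal-parietal lobe,glioblastoma,IV
73,M,25,left temporal lobe and left basal ganglia,glioblastoma,IV
74,M,27,left temporal-occipital lobe,glioblastoma,IV
75,F,40,right occipital lobe,glioblastoma,IV
76,F,64,left parietal lobe,glioblastoma,IV
77,M,71,right temporal lobe,glioblastoma,IV
78,F,22,right frontal lobe,gliomatosis cerebri,IV
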