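code	category
HP:0001939	Abnormality of metabolism/homeostasis
HP:0003119	Abnormality of metabolism/homeostasis
HP:0001987	Abnormality of metabolism/homeostasis
HP:0004322	Abnormality of metabolism/homeostasis
HP:0001197	Abnormality of prenatal development or birth
HP:0001562	Abnormality of prenatal development or birth
HP:0001622	Abnormality of prenatal development or birth
HP:0001511	Abnormality of prenatal development or birth
HP:0001626	Abnormality of the cardiovascular system
HP:0001627	Abnormality of the cardiovascular system
HP:0001631	Abnormality of the cardiovascular system
HP:0001629	Abnormality of the cardiovascular system
HP:0025031	Abnormality of the digestive system
HP:0002020	Abnormality of the digestive system
HP:0002019	Abnormality of the digestive system
HP:0011968	Abnormality of the digestive system
HP:0000598	Abnormality of the ear
HP:0000365	Abnormality of the ear
HP:0000369	Abnormality of the ear
HP:0000400	Abnormality of the ear
HP:0000818	Abnormality of the endocrine system
HP:0000824	Abnormality of the endocrine system
HP:0000851	Abnormality of the endocrine system
HP:0000478	Abnormality of the eye
HP:0000486	Abnormality of the eye
HP:0000639	Abnormality of the eye
HP:0000508	Abnormality of the eye
HP:0000119	Abnormality of the genitourinary system
HP:0000028	Abnormality of the genitourinary system
HP:0000047	Abnormality of the genitourinary system
HP:0000062	Abnormality of the genitourinary system
HP:0000234	Abnormality of the head
HP:0000252	Abnormality of the head
HP:0000256	Abnormality of the head
HP:0001999	Abnormality of the head
HP:0000316	Abnormality of the head
HP:0001574	Abnormality of the integument
HP:0000953	Abnormality of the integument
HP:0001596	Abnormality of the integument
HP:0000958	Abnormality of the integument
HP:0033127	Abnormality of the musculoskeletal system
HP:0001382	Abnormality of the musculoskeletal system
HP:0002650	Abnormality of the musculoskeletal system
HP:0001252	Abnormality of the musculoskeletal system
HP:0002808	Abnormality of the musculoskeletal system
HP:0002086	Abnormality of the respiratory system
HP:0002098	Abnormality of the respiratory system
HP:0002205	Abnormality of the respiratory system
HP:0012443	Abnormal nervous system morphology
HP:0001320	Abnormal nervous system morphology
HP:0001321	Abnormal nervous system morphology
HP:0002079	Abnormal nervous system morphology
HP:0007033	Abnormal nervous system morphology
HP:0012638	Abnormal nervous system physiology
HP:0001250	Abnormal nervous system physiology
HP:0002360	Abnormal nervous system physiology
HP:0001344	Abnormal nervous system physiology
HP:0002194	Abnormal nervous system physiology
HP:0000708	Behavioral abnormality
HP:0000752	Behavioral abnormality
HP:0000739	Behavioral abnormality
HP:0000729	Behavioral abnormality
HP:0000735	Behavioral abnormality
HP:0000728	Behavioral abnormality
HP:0008763	Behavioral abnormality
HP:0000758	Behavioral abnormality
HP:0000717	Behavioral abnormality
HP:0031433	Behavioral abnormality
HP:0000723	Behavioral abnormality
HP:0000753	Behavioral abnormality
HP:0001249	Intellectual disability
HP:0001256	Intellectual disability
HP:0010864	Intellectual disability
HP:0006887	Intellectual disability
HP:0006889	Intellectual disability
HP:0002187	Intellectual disability
HP:0002342	Intellectual disability
HP:0001263	Intellectual disability
HP:0012758	Intellectual disability
HP:0100543	Intellectual disability
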