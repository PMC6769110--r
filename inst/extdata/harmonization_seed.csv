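variant,standard,category,note
EEG C3-A2,EEG C3-A2,EEG,central referential derivation
EEG C4-A1,EEG C4-A1,EEG,central referential derivation
EEG F3-A2,EEG F3-A2,EEG,frontal referential derivation
EEG F4-A1,EEG F4-A1,EEG,frontal referential derivation
EEG O1-A2,EEG O1-A2,EEG,occipital referential derivation
EEG O2-A1,EEG O2-A1,EEG,occipital referential derivation
EEG C3-M2,EEG C3-M2,EEG,mastoid-referenced naming
EEG C4-M1,EEG C4-M1,EEG,mastoid-referenced naming
EEG F3-M2,EEG F3-M2,EEG,mastoid-referenced naming
EEG F4-M1,EEG F4-M1,EEG,mastoid-referenced naming
EEG O1-M2,EEG O1-M2,EEG,mastoid-referenced naming
EEG O2-M1,EEG O2-M1,EEG,mastoid-referenced naming
EEG Fpz-Cz,EEG Fpz-Cz,EEG,midline derivation
EEG Pz-Oz,EEG Pz-Oz,EEG,midline derivation
EOG LOC,EOG LOC,EOG,left outer canthus
EOG ROC,EOG ROC,EOG,right outer canthus
EOG LEFT,EOG LOC,EOG,vendor variant
EOG RIGHT,EOG ROC,EOG,vendor variant
EOG E1-M2,EOG E1-M2,EOG,AASM eye electrode naming
EOG E2-M1,EOG E2-M1,EOG,AASM eye electrode naming
EOG horizontal,EOG horizontal,EOG,combined horizontal channel
EMG Chin,EMG Chin,EMG,chin muscle tone
CHIN1,EMG Chin,EMG,vendor variant
EMG submental,EMG submental,EMG,chin muscle tone
EMG LAT,EMG LAT,EMG,left anterior tibialis
EMG RAT,EMG RAT,EMG,right anterior tibialis
LEGBEINLI,EMG LAT,EMG,vendor variant (German: left leg)
LEGBEINRE,EMG RAT,EMG,vendor variant (German: right leg)
ECG I,ECG I,ECG,lead I
ECG II,ECG II,ECG,lead II
EKG I,ECG I,ECG,spelling variant
EKG II,ECG II,ECG,spelling variant
Resp oro-nasal,Resp oro-nasal,Resp,thermistor airflow
Resp nasal,Resp nasal,Resp,nasal pressure airflow
AIRFLOW,Resp oro-nasal,Resp,vendor variant
FLOW,Resp nasal,Resp,vendor variant
Resp Chest,Resp Chest,Resp,thoracic effort belt
Resp Abdomen,Resp Abdomen,Resp,abdominal effort belt
THOR RES,Resp Chest,Resp,vendor variant
ABDO RES,Resp Abdomen,Resp,vendor variant
SaO2,SaO2,SaO2,pulse oximetry saturation
SPO2,SaO2,SaO2,vendor variant
Snore,Snore,Other,snore microphone or derived
Body position,Body position,Other,position sensor
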