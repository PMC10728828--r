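model_name,task_type,n_params,n_layers,device_name,kwh_per_1e7_tiles
VGG16,classification,1.38e+08,16,quadro_6000,94.53
VGG19,classification,1.44e+08,19,quadro_6000,67.62
ResNet50,classification,25600000,50,quadro_6000,7.067
ResNet101,classification,44700000,101,quadro_6000,17.12
InceptionV3,classification,23900000,48,quadro_6000,19.63
Xception,classification,22900000,71,quadro_6000,25.28
DenseNet121,classification,8100000,121,quadro_6000,1.29
DenseNet201,classification,20200000,201,quadro_6000,24.13
MobileNetV2,classification,3500000,53,quadro_6000,4.22
NASNetMobile,classification,5300000,389,quadro_6000,5.25
EfficientNetB0,classification,5300000,132,quadro_6000,6.924
EfficientNetB4,classification,19500000,258,quadro_6000,23.51
EfficientNetB7,classification,66700000,438,quadro_6000,21.53
ConvNeXtTiny,classification,28600000,59,quadro_6000,15.21
ConvNeXtLarge,classification,197800000,147,quadro_6000,71.87
ConvNeXtXLarge,classification,350200000,151,quadro_6000,143.1
RegNetY064,classification,30600000,64,quadro_6000,14.94
ViT-B16,classification,86600000,12,quadro_6000,37.12
SwinTransformerS,classification,49600000,53,quadro_6000,46.92
CoAtNet2,classification,74700000,64,quadro_6000,73.8
UNet-2D,segmentation,3.1e+07,23,quadro_6000,113.2
UNetPlusPlus,segmentation,36600000,40,quadro_6000,84.89
AttentionUNet,segmentation,34900000,35,quadro_6000,51.31
ResUNet,segmentation,32500000,29,quadro_6000,101.8
DeepLabV3,segmentation,39600000,58,quadro_6000,67.91
DeepLabV3Plus,segmentation,41300000,62,quadro_6000,54.03
FPN,segmentation,25600000,42,quadro_6000,16.25
PSPNet,segmentation,46700000,50,quadro_6000,29.07
LinkNet,segmentation,21800000,34,quadro_6000,19.72
TransUNet,segmentation,105300000,88,quadro_6000,125.7
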